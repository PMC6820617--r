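#' Significance stars for a p-value
#'
#' The field's standard annotation with strict thresholds:
#' `"***"` for p < 0.001, `"**"` for p < 0.01, `"*"` for p < 0.05,
#' `""` otherwise. Boundary values fall in the weaker class
#' (p = 0.05 gets `""`, p = 0.01 gets `"*"`, p = 0.001 gets `"**"`).
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Character vector of star strings.
#' @export
stars_from_p <- function(p) {
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  out[ok] <- ifelse(p[ok] < 0.001, "***",
                    ifelse(p[ok] < 0.01, "**",
                           ifelse(p[ok] < 0.05, "*", "")))
  out
}

#' Summarize replicate RIT50 estimates for one genotype
#'
#' Mean and standard error (sd / sqrt(n)) of the replicate half-lives,
#' mirroring the per-genotype error bars of a triplicate RIT
#' experiment. A single replicate yields `se_s = 0` with
#' `single_replicate = TRUE` flagged.
#'
#' @param estimates List of `half_life_estimate` objects sharing one
#'   genotype, or a data frame of such estimates (columns `genotype`,
#'   `rit50_s`).
#' @return Object of class `genotype_summary` with fields `genotype`,
#'   `mean_rit50_s`, `se_s`, `n_reps`, `values` (the replicate RIT50
#'   vector) and `single_replicate`.
#' @export
summarize_genotype <- function(estimates) {
  if (is.data.frame(estimates)) {
    g <- estimates$genotype
    v <- estimates$rit50_s
  } else {
    stopifnot(length(estimates) >= 1)
    g <- vapply(estimates, `[[`, character(1), "genotype")
    v <- vapply(estimates, `[[`, numeric(1), "rit50_s")
  }
  if (length(v) < 1) stop("need at least one estimate", call. = FALSE)
  if (length(unique(g)) != 1)
    stop("mixed genotypes in summarize_genotype: ",
         paste(unique(g), collapse = ", "), call. = FALSE)
  n <- length(v)
  single <- n == 1
  if (single)
    warning("single replicate for genotype ", g[1],
            ": standard error reported as 0", call. = FALSE)
  structure(list(genotype = g[1],
                 mean_rit50_s = mean(v),
                 se_s = if (single) 0 else stats::sd(v) / sqrt(n),
                 n_reps = n,
                 values = v,
                 single_replicate = single),
            class = "genotype_summary")
}

#' @export
print.genotype_summary <- function(x, ...) {
  cat("<genotype_summary> ", x$genotype, ": mean RIT50 = ",
      signif(x$mean_rit50_s, 5), " s (se ", signif(x$se_s, 4),
      ", n = ", x$n_reps, ")\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.genotype_summary <- function(x, ...) {
  data.frame(genotype = x$genotype, mean_rit50_s = x$mean_rit50_s,
             se_s = x$se_s, n_reps = x$n_reps, stringsAsFactors = FALSE)
}

#' Compare a genotype's RIT50 replicates against the reference
#'
#' Two-sided test on the replicate half-life values. The default is
#' the pooled-variance (Student) two-sample t-test, the conventional
#' choice for triplicate assay comparisons; `method = "welch"` gives
#' the unequal-variance Welch variant (which at n = 3 per group drops
#' to ~2-3 degrees of freedom and has very little power — see the
#' methods vignette), and `method = "z"` a normal test on the
#' difference of means with the two summary standard errors.
#' Degenerate inputs (both groups constant) are handled explicitly:
#' identical means give p = 1, different means p = 0.
#'
#' @param test `genotype_summary` of the genotype under test (must
#'   carry its replicate `values`).
#' @param reference `genotype_summary` of the wild-type reference.
#' @param method `"student"` (default), `"welch"`, or `"z"`.
#' @return Object of class `comparison_result` with fields `genotype`,
#'   `reference`, `diff_s`, `fold_change`, `p_value`, `stars`,
#'   `statistic`, `df` (NA for the z-test), `method`.
#' @export
compare_genotypes <- function(test, reference,
                              method = c("student", "welch", "z")) {
  method <- match.arg(method)
  stopifnot(inherits(test, "genotype_summary"),
            inherits(reference, "genotype_summary"))
  x <- test$values
  y <- reference$values
  if (length(x) < 2 || length(y) < 2)
    stop("insufficient replication: need >= 2 replicates per group ",
         "(got ", length(x), " and ", length(y), ")", call. = FALSE)
  diff_s <- mean(x) - mean(y)
  fold <- mean(x) / mean(y)
  if (method %in% c("student", "welch")) {
    vx <- stats::var(x) / length(x)
    vy <- stats::var(y) / length(y)
    if (vx + vy == 0) {
      stat <- if (diff_s == 0) 0 else sign(diff_s) * Inf
      df <- NA_real_
      p <- if (diff_s == 0) 1 else 0
    } else {
      tt <- stats::t.test(x, y, var.equal = method == "student")
      stat <- unname(tt$statistic)
      df <- unname(tt$parameter)
      p <- tt$p.value
    }
  } else {
    se <- sqrt(test$se_s^2 + reference$se_s^2)
    if (se == 0) {
      stat <- if (diff_s == 0) 0 else sign(diff_s) * Inf
      p <- if (diff_s == 0) 1 else 0
    } else {
      stat <- diff_s / se
      p <- 2 * stats::pnorm(-abs(stat))
    }
    df <- NA_real_
  }
  structure(list(genotype = test$genotype, reference = reference$genotype,
                 diff_s = diff_s, fold_change = fold,
                 p_value = p, stars = stars_from_p(p),
                 statistic = stat, df = df, method = method),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result> ", x$genotype, " vs ", x$reference,
      ": diff = ", signif(x$diff_s, 4), " s, fold = ",
      signif(x$fold_change, 4), ", p = ", signif(x$p_value, 3),
      " ", x$stars, "\n", sep = "")
  invisible(x)
}

#' Rank genotypes by shatter resistance against a reference
#'
#' Orders genotype summaries by mean RIT50 (descending; ties broken by
#' genotype label), annotates each with fold change versus the
#' reference, the comparison p-value, its Holm adjustment across all
#' non-reference genotypes, and significance stars. The reference row
#' is flagged and carries no p-value.
#'
#' @param summaries List of `genotype_summary` objects (unique
#'   genotypes).
#' @param reference Label of the reference genotype; must be present.
#' @param method Comparison method passed to [compare_genotypes()].
#' @return Data frame with columns `genotype`, `n_reps`,
#'   `mean_rit50_s`, `se_s`, `diff_s`, `fold_change`, `p_value`,
#'   `p_holm`, `stars`, `is_reference`.
#' @export
rank_genotypes <- function(summaries, reference,
                           method = c("student", "welch", "z")) {
  method <- match.arg(method)
  labels <- vapply(summaries, `[[`, character(1), "genotype")
  if (anyDuplicated(labels))
    stop("duplicate genotype summaries: ",
         paste(labels[duplicated(labels)], collapse = ", "), call. = FALSE)
  if (!reference %in% labels)
    stop("reference genotype '", reference, "' not found; available: ",
         paste(sort(labels), collapse = ", "), call. = FALSE)
  ref <- summaries[[match(reference, labels)]]
  rows <- lapply(summaries, function(s) {
    base <- as.data.frame(s)
    if (s$genotype == reference) {
      cbind(base, diff_s = 0, fold_change = 1, p_value = NA_real_,
            is_reference = TRUE)
    } else {
      cmp <- tryCatch(compare_genotypes(s, ref, method = method),
                      error = function(e) NULL)
      cbind(base,
            diff_s = s$mean_rit50_s - ref$mean_rit50_s,
            fold_change = s$mean_rit50_s / ref$mean_rit50_s,
            p_value = if (is.null(cmp)) NA_real_ else cmp$p_value,
            is_reference = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$p_holm <- NA_real_
  idx <- which(!out$is_reference & !is.na(out$p_value))
  if (length(idx))
    out$p_holm[idx] <- stats::p.adjust(out$p_value[idx], method = "holm")
  out$stars <- stars_from_p(out$p_value)
  out$stars[is.na(out$stars)] <- ""
  # radix method: byte-wise label collation, stable across locales
  out <- out[order(-out$mean_rit50_s, out$genotype, method = "radix"), ]
  rownames(out) <- NULL
  out[, c("genotype", "n_reps", "mean_rit50_s", "se_s", "diff_s",
          "fold_change", "p_value", "p_holm", "stars", "is_reference")]
}

#' Estimate per-assay half-lives across a whole dataset
#'
#' Convenience pipeline step: fits the decay model and extracts the
#' RIT50 for every assay in a dataset.
#'
#' @param dataset An `rit_dataset`.
#' @param options A [fit_options()] list applied to every fit.
#' @return List with `estimates` (list of `half_life_estimate`),
#'   `fits` (list of `decay_fit`), `table` (data frame, one row per
#'   converged assay) and `failed` (labels of assays that could not be
#'   fitted, with reasons).
#' @export
estimate_half_lives <- function(dataset, options = fit_options()) {
  fits <- list()
  ests <- list()
  failed <- character(0)
  for (a in dataset$assays) {
    label <- paste0(a$genotype, "/", a$replicate_id)
    res <- tryCatch({
      f <- fit_decay(a, options)
      list(fit = f, est = half_life(f))
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      failed <- c(failed, paste0(label, ": ", res))
    } else {
      fits[[length(fits) + 1L]] <- res$fit
      ests[[length(ests) + 1L]] <- res$est
    }
  }
  tab <- results_to_df(ests)
  list(estimates = ests, fits = fits, table = tab, failed = failed)
}

#' Summaries for every genotype in a half-life table
#'
#' @param estimates List of `half_life_estimate` objects or the
#'   `table` data frame from [estimate_half_lives()].
#' @return Named list of `genotype_summary`, one per genotype.
#' @export
summarize_all_genotypes <- function(estimates) {
  df <- results_to_df(estimates)
  out <- lapply(split(df, df$genotype), summarize_genotype)
  out[unique(df$genotype)]
}
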