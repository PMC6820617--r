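#' Configuration for the stochastic RIT simulator
#'
#' Describes the generative world for one genotype: `n_pods`
#' independent pods whose break-times are exponential with rate
#' `true_b` (so the intact count at time t is marginally
#' Binomial(n_pods, exp(-true_b * t)) and the true half-life is
#' log(2)/true_b), observed on the finite grid
#' t = 0, interval_s, ..., n_intervals * interval_s. A Weibull hook
#' (`break_dist = "weibull"`) generates misspecified break-times whose
#' median still equals the exponential half-life.
#'
#' @param genotype Genotype label for the simulated assays.
#' @param true_b Decay rate in 1/s; give either this or
#'   `true_half_life_s` (= log(2)/true_b).
#' @param true_half_life_s Alternative parameterization of the rate.
#' @param n_pods Pods per assay (protocol default 20).
#' @param interval_s Observation spacing in seconds (protocol
#'   default 8).
#' @param n_intervals Number of shaking intervals; the grid has
#'   `n_intervals + 1` observations including t = 0 (default 15,
#'   i.e. 0..120 s at 8 s).
#' @param n_reps Replicate assays per genotype (protocol default 3).
#' @param seed Integer master seed; all replicate seeds derive from it.
#' @param break_dist `"exponential"` (default, matches the analysis
#'   model) or `"weibull"`.
#' @param weibull_shape Shape for the Weibull hook (1 = exponential).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(genotype = "WT", true_b = NULL,
                       true_half_life_s = NULL, n_pods = 20L,
                       interval_s = 8, n_intervals = 15L, n_reps = 3L,
                       seed = 1L,
                       break_dist = c("exponential", "weibull"),
                       weibull_shape = 1) {
  break_dist <- match.arg(break_dist)
  if (is.null(true_b)) {
    if (is.null(true_half_life_s))
      stop("give true_b or true_half_life_s", call. = FALSE)
    true_b <- log(2) / true_half_life_s
  }
  stopifnot(n_pods >= 1, true_b > 0, interval_s > 0, n_intervals >= 2,
            n_reps >= 1, weibull_shape > 0)
  structure(list(genotype = as.character(genotype), true_b = true_b,
                 n_pods = as.integer(n_pods),
                 interval_s = as.numeric(interval_s),
                 n_intervals = as.integer(n_intervals),
                 n_reps = as.integer(n_reps), seed = as.integer(seed),
                 break_dist = break_dist,
                 weibull_shape = weibull_shape),
            class = "sim_config")
}

# Deterministic 31-bit seed from a base seed and string labels
# (polynomial string hash; keeps derived seeds inside R's integer range).
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (s in as.character(c(...))) {
    for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
  }
  as.integer(h)
}

#' Simulate one RIT assay
#'
#' Each pod draws an independent break-time; the intact count at grid
#' time t is the number of pods with break-time > t (pathwise, so
#' counts are non-increasing within the assay, as when the same pods
#' are re-inspected). The assay includes the (0, n_pods) anchor and is
#' deterministic given `(config$seed, config$genotype, replicate_id)`.
#'
#' @param config A [sim_config()].
#' @param replicate_id Replicate label (default "r1").
#' @return An [rit_assay()]; right-truncated assays (pods surviving the
#'   last interval) are returned without the truncation warning.
#' @export
simulate_assay <- function(config, replicate_id = "r1") {
  stopifnot(inherits(config, "sim_config"))
  old <- local_seed(derive_seed(config$seed, config$genotype, replicate_id))
  on.exit(restore_seed(old))
  breaks <- if (config$break_dist == "exponential") {
    stats::rexp(config$n_pods, rate = config$true_b)
  } else {
    # scale chosen so the median break-time stays log(2)/true_b
    med <- log(2) / config$true_b
    stats::rweibull(config$n_pods, shape = config$weibull_shape,
                    scale = med / log(2)^(1 / config$weibull_shape))
  }
  times <- seq(0, by = config$interval_s,
               length.out = config$n_intervals + 1L)
  counts <- vapply(times, function(tt) sum(breaks > tt), numeric(1))
  suppressWarnings(
    rit_assay(config$genotype, replicate_id, time_s = times,
              intact_count = counts, initial_count = config$n_pods,
              interval_s = config$interval_s))
}

#' Simulate a multi-genotype RIT dataset
#'
#' Generates `n_reps` replicate assays per config (replicate ids
#' `r1..rn`) with seeds derived deterministically from each config's
#' seed, genotype label and replicate index.
#'
#' @param configs A single [sim_config()] or a list of them with
#'   unique genotype labels.
#' @param reference Label stored as the dataset's reference genotype
#'   (default: the first config's genotype).
#' @return An [rit_dataset()].
#' @export
simulate_dataset <- function(configs, reference = NULL) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  labels <- vapply(configs, `[[`, character(1), "genotype")
  if (anyDuplicated(labels))
    stop("duplicate genotype labels across sim configs: ",
         paste(labels[duplicated(labels)], collapse = ", "),
         call. = FALSE)
  if (is.null(reference)) reference <- labels[1]
  assays <- list()
  for (cfg in configs) {
    for (r in seq_len(cfg$n_reps)) {
      assays[[length(assays) + 1L]] <-
        simulate_assay(cfg, paste0("r", r))
    }
  }
  rit_dataset(assays, reference_genotype = reference)
}

#' True parameters of a simulation, for recovery scoring
#'
#' @param configs A `sim_config` or list of them.
#' @return Data frame with `genotype`, `true_b`, `true_half_life_s`,
#'   `n_pods`, `n_reps`.
#' @export
sim_manifest <- function(configs) {
  if (inherits(configs, "sim_config")) configs <- list(configs)
  do.call(rbind, lapply(configs, function(cfg) {
    data.frame(genotype = cfg$genotype, true_b = cfg$true_b,
               true_half_life_s = log(2) / cfg$true_b,
               n_pods = cfg$n_pods, interval_s = cfg$interval_s,
               n_intervals = cfg$n_intervals, n_reps = cfg$n_reps,
               seed = cfg$seed, break_dist = cfg$break_dist,
               stringsAsFactors = FALSE)
  }))
}

#' Simulation study of RIT50 estimator bias, RMSE and CI coverage
#'
#' Repeats simulate -> fit -> half-life `n_sims` times under one
#' configuration and scores the estimates against the true half-life
#' log(2)/true_b: mean bias, RMSE, empirical coverage of the
#' delta-method confidence interval at `level`, and the fraction of
#' simulations where the fit failed or did not converge
#' (non-convergence is reported, never thrown).
#'
#' @param config A [sim_config()]; each simulation uses a seed derived
#'   from `config$seed` and the simulation index.
#' @param n_sims Number of simulated assays (>= 100).
#' @param level CI level scored for coverage (default 0.95).
#' @param options [fit_options()] for the fits.
#' @return List of class `recovery_report`: `true_half_life_s`, `bias`,
#'   `rmse`, `coverage`, `frac_nonconverged`, `n_sims`, `estimates`
#'   (vector with NA for failed fits).
#' @export
recovery_experiment <- function(config, n_sims = 1000L, level = 0.95,
                                options = fit_options(level = level)) {
  stopifnot(n_sims >= 100)
  true_hl <- log(2) / config$true_b
  est <- rep(NA_real_, n_sims)
  cover <- rep(NA, n_sims)
  for (i in seq_len(n_sims)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, "sim", i)
    a <- simulate_assay(cfg_i, "r1")
    hl <- tryCatch({
      f <- fit_decay(a, options)
      if (!f$converged) NULL else half_life(f, level = level)
    }, error = function(e) NULL)
    if (!is.null(hl)) {
      est[i] <- hl$rit50_s
      cover[i] <- hl$ci_low_s <= true_hl && true_hl <= hl$ci_high_s
    }
  }
  ok <- is.finite(est)
  structure(list(true_half_life_s = true_hl,
                 bias = mean(est[ok]) - true_hl,
                 rmse = sqrt(mean((est[ok] - true_hl)^2)),
                 coverage = mean(cover[ok]),
                 frac_nonconverged = 1 - mean(ok),
                 n_sims = n_sims, level = level,
                 estimates = est),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report> true RIT50 = ", signif(x$true_half_life_s, 5),
      " s over ", x$n_sims, " sims\n",
      "  bias = ", signif(x$bias, 4), " s, rmse = ", signif(x$rmse, 4),
      " s, ", round(100 * x$level), "% CI coverage = ",
      signif(x$coverage, 4), ", non-converged = ",
      signif(x$frac_nonconverged, 3), "\n", sep = "")
  invisible(x)
}
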