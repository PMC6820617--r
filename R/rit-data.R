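#' Construct a single RIT assay
#'
#' An assay is one container of pods shaken in the Random Impact Test:
#' `initial_count` undamaged pods (protocol default 20) are shaken in
#' fixed-length intervals (protocol default 8 s) and the number of pods
#' that have not yet released any seed is recorded after each interval.
#'
#' If no observation at time 0 is supplied, the protocol-guaranteed row
#' `(0, initial_count)` is synthesized and the assay is flagged with
#' `time_zero_synthesized = TRUE`.
#'
#' @param genotype Genotype label (free text).
#' @param replicate_id Replicate label within the genotype (free text).
#' @param time_s Numeric vector of cumulative shaking times in seconds.
#' @param intact_count Integer vector of intact-pod counts, same length
#'   as `time_s`.
#' @param initial_count Number of pods at the start of the assay
#'   (default 20).
#' @param interval_s Nominal observation spacing in seconds (default 8).
#'   Metadata only; the fit uses the recorded times.
#' @param validate If `TRUE` (default), stop on any invariant violation.
#'
#' @return An object of class `rit_assay`: a list with the metadata
#'   fields above and an `observations` data frame
#'   (`time_s`, `intact_count`) sorted by time.
#' @export
#' @examples
#' a <- rit_assay("WT", "r1", time_s = seq(0, 32, 8),
#'                intact_count = c(20, 14, 9, 6, 3))
#' validate_assay(a)
rit_assay <- function(genotype, replicate_id, time_s, intact_count,
                      initial_count = 20L, interval_s = 8,
                      validate = TRUE) {
  stopifnot(length(time_s) == length(intact_count),
            length(genotype) == 1L, length(replicate_id) == 1L)
  ord <- order(time_s)
  obs <- data.frame(time_s = as.numeric(time_s)[ord],
                    intact_count = as.numeric(intact_count)[ord])
  synthesized <- FALSE
  if (!any(obs$time_s == 0)) {
    obs <- rbind(data.frame(time_s = 0, intact_count = as.numeric(initial_count)),
                 obs)
    synthesized <- TRUE
  }
  x <- structure(
    list(genotype = as.character(genotype),
         replicate_id = as.character(replicate_id),
         initial_count = as.numeric(initial_count),
         interval_s = as.numeric(interval_s),
         observations = obs,
         time_zero_synthesized = synthesized),
    class = "rit_assay")
  if (validate) {
    v <- validate_assay(x)
    if (length(v) > 0)
      stop("invalid RIT assay [", genotype, "/", replicate_id, "]: ",
           paste(v, collapse = "; "), call. = FALSE)
    if (utils::tail(obs$intact_count, 1) > 0)
      warning("assay [", genotype, "/", replicate_id,
              "] is right-truncated: last intact_count = ",
              utils::tail(obs$intact_count, 1), " > 0", call. = FALSE)
  }
  x
}

#' @export
print.rit_assay <- function(x, ...) {
  cat("<rit_assay> ", x$genotype, "/", x$replicate_id,
      ": ", nrow(x$observations), " observations, ",
      x$initial_count, " pods, ", x$interval_s, "-s interval\n", sep = "")
  invisible(x)
}

#' Check an RIT assay against its structural invariants
#'
#' The validator never throws: it returns a character vector of
#' violation descriptions, empty when the assay is well formed. Checked
#' rules: non-negative times and counts, strictly increasing times,
#' non-increasing counts (pods cannot un-break), counts bounded by
#' `initial_count`, and `intact_count == initial_count` at time 0.
#'
#' @param assay An `rit_assay` object.
#' @return Character vector of findings (empty if valid).
#' @export
validate_assay <- function(assay) {
  obs <- assay$observations
  t <- obs$time_s
  y <- obs$intact_count
  out <- character(0)
  bad <- which(t < 0)
  if (length(bad))
    out <- c(out, paste0("negative time_s at row(s) ",
                         paste(bad, collapse = ",")))
  bad <- which(y < 0)
  if (length(bad))
    out <- c(out, paste0("negative intact_count at row(s) ",
                         paste(bad, collapse = ",")))
  if (any(y != round(y)))
    out <- c(out, "non-integer intact_count")
  if (length(t) > 1) {
    d <- which(diff(t) <= 0)
    for (i in d) {
      if (t[i + 1] == t[i])
        out <- c(out, paste0("duplicate time_s = ", t[i],
                             " at rows ", i, " and ", i + 1))
      else
        out <- c(out, paste0("time_s not increasing at rows ",
                             i, " and ", i + 1))
    }
    d <- which(diff(y) > 0)
    for (i in d)
      out <- c(out, paste0("non-monotone intact_count: ", y[i], " -> ",
                           y[i + 1], " at rows ", i, " and ", i + 1,
                           " (t = ", t[i], ", ", t[i + 1], ")"))
  }
  bad <- which(y > assay$initial_count)
  if (length(bad))
    out <- c(out, paste0("intact_count exceeds initial_count (",
                         assay$initial_count, ") at row(s) ",
                         paste(bad, collapse = ",")))
  i0 <- which(t == 0)
  if (length(i0) && any(y[i0] != assay$initial_count))
    out <- c(out, paste0("intact_count at time 0 is ", y[i0[1]],
                         " but initial_count is ", assay$initial_count))
  out
}

#' Construct an RIT dataset (a set of assays with a reference genotype)
#'
#' @param assays List of `rit_assay` objects with unique
#'   `(genotype, replicate_id)` pairs.
#' @param reference_genotype Label of the wild-type/control genotype,
#'   or `NA` when no comparison is intended.
#' @return Object of class `rit_dataset`.
#' @export
rit_dataset <- function(assays, reference_genotype = NA_character_) {
  stopifnot(all(vapply(assays, inherits, logical(1), "rit_assay")))
  keys <- vapply(assays, function(a) paste(a$genotype, a$replicate_id, sep = "\r"),
                 character(1))
  if (anyDuplicated(keys))
    stop("duplicate (genotype, replicate_id) pairs: ",
         paste(gsub("\r", "/", keys[duplicated(keys)]), collapse = ", "),
         call. = FALSE)
  structure(list(assays = assays,
                 reference_genotype = as.character(reference_genotype)),
            class = "rit_dataset")
}

#' @export
print.rit_dataset <- function(x, ...) {
  g <- vapply(x$assays, `[[`, character(1), "genotype")
  cat("<rit_dataset> ", length(x$assays), " assays, ",
      length(unique(g)), " genotypes",
      if (!is.na(x$reference_genotype))
        paste0(", reference = ", x$reference_genotype), "\n", sep = "")
  invisible(x)
}

#' @export
length.rit_dataset <- function(x) length(x$assays)

#' Genotype labels present in a dataset
#' @param dataset An `rit_dataset`.
#' @return Character vector of unique genotype labels.
#' @export
genotypes <- function(dataset) {
  unique(vapply(dataset$assays, `[[`, character(1), "genotype"))
}

#' Convert a wide bench sheet to the long RIT table format
#'
#' Bench sheets often record one column per inspection time. This
#' converter takes a data frame with `genotype`, `replicate` and one
#' count column per time point (column names parseable as numbers,
#' optionally prefixed, e.g. `t8` or `"8"`), and returns the long
#' format consumed by [read_rit_table()].
#'
#' @param wide Data frame in wide format.
#' @param time_prefix Prefix stripped from count column names before
#'   numeric conversion (default "t"; a bare numeric name also works).
#' @return Long data frame with columns
#'   `genotype`, `replicate`, `time_s`, `intact_count`.
#' @export
rit_wide_to_long <- function(wide, time_prefix = "t") {
  stopifnot(all(c("genotype", "replicate") %in% names(wide)))
  meta <- intersect(c("genotype", "replicate", "initial_count", "interval_s"),
                    names(wide))
  tcols <- setdiff(names(wide), meta)
  times <- suppressWarnings(as.numeric(sub(paste0("^", time_prefix), "", tcols)))
  if (any(is.na(times)))
    stop("cannot parse time from column(s): ",
         paste(tcols[is.na(times)], collapse = ", "), call. = FALSE)
  long <- do.call(rbind, lapply(seq_along(tcols), function(i) {
    d <- wide[meta]
    d$time_s <- times[i]
    d$intact_count <- wide[[tcols[i]]]
    d
  }))
  long <- long[order(long$genotype, long$replicate, long$time_s), ]
  rownames(long) <- NULL
  long
}
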