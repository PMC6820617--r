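#' Read a long-format RIT assay table
#'
#' Expects a delimited UTF-8 text file with a header row and columns
#' `genotype`, `replicate`, `time_s`, `intact_count`; optional columns
#' `initial_count` and `interval_s` set per-assay metadata (constant
#' within an assay). Rows are grouped into assays by
#' `(genotype, replicate)` and sorted by time. Each assay is validated;
#' in strict mode any violation aborts the read, in lenient mode the
#' offending assays are dropped with a warning and listed in the
#' `skipped` attribute of the result.
#'
#' @param path Path to the table.
#' @param sep Field separator: `","` (default) or `"\t"`; `NULL`
#'   auto-detects from the header line.
#' @param reference_genotype Optional wild-type label stored on the
#'   returned dataset.
#' @param strict If `TRUE` (default) invariant violations are errors.
#' @return An [rit_dataset()].
#' @export
read_rit_table <- function(path, sep = ",", reference_genotype = NA_character_,
                           strict = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    hdr <- readLines(path, n = 1L)
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, encoding = "UTF-8",
                          colClasses = NA, check.names = TRUE)
  rit_dataset_from_df(df, reference_genotype = reference_genotype,
                      strict = strict)
}

#' Build an RIT dataset from a long-format data frame
#'
#' Same contract as [read_rit_table()] but starting from an in-memory
#' data frame (e.g. the output of [rit_wide_to_long()] or
#' [simulate_dataset()] written/read elsewhere).
#'
#' @inheritParams read_rit_table
#' @param df Data frame with the long-format columns.
#' @return An [rit_dataset()].
#' @export
rit_dataset_from_df <- function(df, reference_genotype = NA_character_,
                                strict = TRUE) {
  required <- c("genotype", "replicate", "time_s", "intact_count")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) stop("no assays: input table is empty", call. = FALSE)
  for (col in c("time_s", "intact_count", "initial_count", "interval_s")) {
    if (!col %in% names(df)) next
    v <- df[[col]]
    if (is.character(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(conv) & !is.na(v))
      if (length(bad))
        stop("non-numeric ", col, " at data row(s) ",
             paste(bad, collapse = ","), ": ",
             paste(unique(v[bad]), collapse = ", "), call. = FALSE)
      df[[col]] <- conv
    }
  }
  key <- paste(df$genotype, df$replicate, sep = "\r")
  assays <- list()
  skipped <- character(0)
  for (k in unique(key)) {
    rows <- df[key == k, , drop = FALSE]
    label <- paste0(rows$genotype[1], "/", rows$replicate[1])
    ic <- if ("initial_count" %in% names(rows)) rows$initial_count[1] else 20L
    iv <- if ("interval_s" %in% names(rows)) rows$interval_s[1] else 8
    a <- tryCatch(
      rit_assay(rows$genotype[1], as.character(rows$replicate[1]),
                time_s = rows$time_s, intact_count = rows$intact_count,
                initial_count = ic, interval_s = iv),
      error = function(e) e)
    if (inherits(a, "error")) {
      if (strict) stop(conditionMessage(a), call. = FALSE)
      skipped <- c(skipped, label)
      warning("skipping assay [", label, "]: ", conditionMessage(a),
              call. = FALSE)
    } else {
      assays[[length(assays) + 1L]] <- a
    }
  }
  if (length(assays) == 0) stop("no assays: all rows invalid", call. = FALSE)
  out <- rit_dataset(assays, reference_genotype = reference_genotype)
  attr(out, "skipped") <- skipped
  out
}

#' Write an RIT dataset back to the long table format
#'
#' Inverse of [read_rit_table()]: produces a long CSV (or TSV) that
#' round-trips field-by-field through the reader. Synthesized time-zero
#' rows are written out like any other row.
#'
#' @param dataset An `rit_dataset`.
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_rit_table <- function(dataset, path, sep = ",") {
  df <- as.data.frame(dataset)
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
as.data.frame.rit_dataset <- function(x, ...) {
  do.call(rbind, lapply(x$assays, function(a) {
    data.frame(genotype = a$genotype, replicate = a$replicate_id,
               time_s = a$observations$time_s,
               intact_count = a$observations$intact_count,
               initial_count = a$initial_count,
               interval_s = a$interval_s,
               stringsAsFactors = FALSE)
  }))
}

#' Write a results table (half-life estimates or genotype summaries)
#'
#' Writes a homogeneous list of result records, or a result data frame,
#' as a delimited table with a stable column order and full floating
#' precision (15 significant digits), so that values survive a
#' write/read round trip to within representation precision.
#'
#' @param records A list of `half_life_estimate` or `genotype_summary`
#'   objects (all the same class), or a data frame.
#' @param path Output file path.
#' @param sep Field separator (default comma).
#' @return `path`, invisibly.
#' @export
write_results_table <- function(records, path, sep = ",") {
  df <- results_to_df(records)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    trimws(formatC(v, digits = 15, format = "g")))
  utils::write.table(df, path, sep = sep, row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path Path to the table.
#' @param sep Field separator (default comma).
#' @return Data frame with the table's columns.
#' @export
read_results_table <- function(path, sep = ",") {
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, encoding = "UTF-8")
}

results_to_df <- function(records) {
  if (is.data.frame(records)) return(records)
  stopifnot(is.list(records))
  if (length(records) == 0)
    return(data.frame(genotype = character(0), replicate = character(0),
                      rit50_s = numeric(0), se_s = numeric(0),
                      ci_low_s = numeric(0), ci_high_s = numeric(0),
                      level = numeric(0)))
  cls <- unique(vapply(records, function(r) class(r)[1], character(1)))
  if (length(cls) != 1)
    stop("records must be homogeneous; got classes: ",
         paste(cls, collapse = ", "), call. = FALSE)
  do.call(rbind, lapply(records, as.data.frame))
}
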