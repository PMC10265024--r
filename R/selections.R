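#' Read a Raven-style selection table
#'
#' Parses the tab-separated selection-table dialect used by Raven: a header
#' row with at least `Begin Time (s)` and `End Time (s)` columns. Optional
#' `Low Freq (Hz)`, `High Freq (Hz)` and `label` columns are mapped to tidy
#' names; any further columns are carried through untouched.
#'
#' @param path Path to a tab-separated selection table.
#' @return A tibble with columns `start`, `end` (seconds) and, when present,
#'   `low_freq`, `high_freq` (Hz), `label`, plus any extra columns.
#' @export
read_selection_table <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("Begin Time (s)", "End Time (s)")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    stop("selection table is missing column(s): ",
         paste(sQuote(missing), collapse = ", "))
  ren <- c("Begin Time (s)" = "start", "End Time (s)" = "end",
           "Low Freq (Hz)" = "low_freq", "High Freq (Hz)" = "high_freq",
           "label" = "label")
  present <- intersect(names(ren), names(df))
  names(df)[match(present, names(df))] <- ren[present]
  as_tibble(df)
}

#' Write a Raven-style selection table
#'
#' Inverse of [read_selection_table()]; numeric times are written with six
#' decimal places so that a write/read round trip is exact at that precision.
#'
#' @param selections Tibble with `start` and `end` columns (seconds) and
#'   optionally `low_freq`, `high_freq`, `label` and extra columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_selection_table <- function(selections, path) {
  stopifnot(all(c("start", "end") %in% names(selections)))
  df <- as.data.frame(selections)
  ren <- c(start = "Begin Time (s)", end = "End Time (s)",
           low_freq = "Low Freq (Hz)", high_freq = "High Freq (Hz)",
           label = "label")
  present <- intersect(names(ren), names(df))
  names(df)[match(present, names(df))] <- ren[present]
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.6f", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
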