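#' Write a threshold table to CSV
#'
#' Emits a \code{\link{threshold_table}} as a plain comma-separated file with
#' a header row (\code{n,L_a2,U_a2,...}). Decimal points are used by default;
#' \code{decimal_comma = TRUE} switches to the decimal-comma convention of
#' some printed tables (fields are then separated by semicolons, as in
#' \code{write.csv2}).
#'
#' @param table A \code{\link{threshold_table}}.
#' @param path Output file path.
#' @param decimal_comma Use "," as the decimal separator (and ";" as the field
#'   separator).
#' @return \code{path}, invisibly.
#' @export
write_threshold_table <- function(table, path, decimal_comma = FALSE) {
  if (!inherits(table, "threshold_table")) {
    stop("`table` must be created with threshold_table()", call. = FALSE)
  }
  df <- as.data.frame(table)
  if (decimal_comma) {
    utils::write.csv2(df, path, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read a threshold table written by write_threshold_table
#'
#' @param path CSV file path.
#' @param decimal_comma File uses decimal commas / semicolon separators.
#' @return A data frame with the same columns as the written table.
#' @export
read_threshold_table <- function(path, decimal_comma = FALSE) {
  if (decimal_comma) {
    utils::read.csv2(path, check.names = FALSE)
  } else {
    utils::read.csv(path, check.names = FALSE)
  }
}

#' Read per-subject hit counts from a text file
#'
#' Expects one integer per line; a single non-numeric first line is treated
#' as a header and skipped.
#'
#' @param path File path.
#' @return Integer vector of hit counts.
#' @export
read_hits <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("no hit counts in file", call. = FALSE)
  if (is.na(suppressWarnings(as.numeric(lines[1])))) lines <- lines[-1]
  x <- suppressWarnings(as.numeric(lines))
  if (anyNA(x) || any(x != as.integer(x))) {
    stop("hit-count file must contain one integer per line", call. = FALSE)
  }
  as.integer(x)
}
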