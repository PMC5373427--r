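#' Read a numeric observations-by-features matrix from a delimited file
#'
#' Reads a rectangular numeric table (CSV/TSV) with observations in rows.
#' An optional header row and an optional label column are supported; parse
#' failures report the offending row and column.
#'
#' @param path path to the file.
#' @param delimiter field delimiter; default \code{","}, use \code{"\t"} for
#'   TSV. \code{NULL} picks by file extension (\code{.tsv}/\code{.tab} =>
#'   tab, otherwise comma).
#' @param header \code{TRUE}, \code{FALSE}, or \code{"auto"} (default):
#'   treat the first row as column names when any of its non-label fields is
#'   not numeric.
#' @param labelCol integer index of a column holding row labels, or
#'   \code{NULL} (default) for none.
#' @return numeric matrix with row names taken from the label column when
#'   declared.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("0,0", "1,0", "10,0"), f)
#' readMatrix(f)
#' @export
readMatrix <- function(path, delimiter = ",", header = "auto",
                       labelCol = NULL) {
  if (!file.exists(path))
    stop(sprintf("file not found: %s", path))
  if (is.null(delimiter))
    delimiter <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE))
      "\t" else ","
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop(sprintf("parse error: %s is empty", path))
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[1L])[1L]
    stop(sprintf(
      "parse error: ragged table, row %d has %d fields but row 1 has %d",
      bad, widths[bad], widths[1L]))
  }
  dataCols <- setdiff(seq_len(widths[1L]), labelCol)
  if (!length(dataCols))
    stop("no data columns left after removing the label column")
  isNum <- function(v) !is.na(suppressWarnings(as.numeric(v)))
  if (identical(header, "auto"))
    header <- !all(isNum(fields[[1L]][dataCols]))
  colNames <- NULL
  if (isTRUE(header)) {
    colNames <- fields[[1L]][dataCols]
    fields <- fields[-1L]
    if (!length(fields))
      stop(sprintf("parse error: %s has a header but no data rows", path))
  }
  rowLabels <- if (!is.null(labelCol))
    vapply(fields, `[`, character(1), labelCol) else NULL
  mat <- matrix(NA_real_, nrow = length(fields), ncol = length(dataCols))
  for (i in seq_along(fields)) {
    v <- suppressWarnings(as.numeric(fields[[i]][dataCols]))
    if (anyNA(v)) {
      j <- dataCols[which(is.na(v))[1L]]
      stop(sprintf(
        "parse error: non-numeric value '%s' at row %d, column %d",
        fields[[i]][j], i + isTRUE(header), j))
    }
    mat[i, ] <- v
  }
  rownames(mat) <- rowLabels
  colnames(mat) <- colNames
  mat
}

#' Write cluster assignments to CSV
#'
#' @param assignment integer cluster labels as returned by
#'   \code{\link{cutToK}}; names, when present, are written as the label
#'   column.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAssignments <- function(assignment, path) {
  labs <- names(assignment)
  if (is.null(labs)) labs <- seq_along(assignment)
  utils::write.csv(
    data.frame(label = labs, cluster_id = as.integer(assignment)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
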