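#' Cell x channel spectra matrix
#'
#' The unit record of decoding: one row of per-channel mean pixel
#' intensities per segmented cell.
#'
#' @param cell_ids Positive integer ids, one per row, strictly increasing
#'   order is not required but ids must be unique.
#' @param matrix Numeric n_cells x n_channels matrix, entries >= 0.
#' @param truth_labels Optional character vector of ground-truth FP names.
#' @param source Provenance string.
#' @return An object of class \code{cell_spectra}.
#' @export
cell_spectra <- function(cell_ids, matrix, truth_labels = NULL,
                         source = "unknown") {
  matrix <- as.matrix(matrix)
  cell_ids <- as.integer(cell_ids)
  if (length(cell_ids) != nrow(matrix))
    stop("cell_ids length must equal the number of matrix rows")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (any(cell_ids <= 0)) stop("cell ids must be positive integers")
  if (any(matrix < 0)) stop("intensities must be non-negative")
  if (!is.null(truth_labels) && length(truth_labels) != nrow(matrix))
    stop("truth_labels length must equal the number of cells")
  structure(list(cell_ids = cell_ids, matrix = unname(matrix),
                 truth_labels = truth_labels, source = source),
            class = "cell_spectra")
}

#' @export
print.cell_spectra <- function(x, ...) {
  cat(sprintf("Cell spectra: %d cells x %d channels%s (source: %s)\n",
              nrow(x$matrix), ncol(x$matrix),
              if (is.null(x$truth_labels)) "" else ", with truth labels",
              x$source))
  invisible(x)
}

#' Number of cells
#' @param x A \code{cell_spectra} object.
#' @return Integer cell count.
#' @export
n_cells <- function(x) {
  stopifnot(inherits(x, "cell_spectra"))
  nrow(x$matrix)
}

channel_colnames <- function(n) sprintf("ch%03d", seq_len(n))

FORMAT_HEADER <- "# specdex-format v1"

check_format_version <- function(path) {
  first <- readLines(path, n = 1)
  if (startsWith(first, "#")) {
    if (!grepl("specdex-format v1(\\.|$|\\s)", first))
      stop(sprintf("%s: unsupported format version line: %s", path, first))
    return(TRUE)   # skip the comment line when reading
  }
  FALSE
}

#' Read / write cell spectra as CSV
#'
#' Schema: a \code{# specdex-format v1} comment line, then a header
#' \code{cell_id,truth_label,ch001..chNNN} (the \code{truth_label} column is
#' empty when no ground truth exists), one row per cell.
#'
#' @param cells A \code{\link{cell_spectra}} object (for writing).
#' @param path CSV file path.
#' @return \code{read_cell_spectra} returns a \code{cell_spectra} object.
#' @export
write_cell_spectra <- function(cells, path) {
  stopifnot(inherits(cells, "cell_spectra"))
  df <- data.frame(cell_id = cells$cell_ids,
                   truth_label = if (is.null(cells$truth_labels)) ""
                                 else cells$truth_labels,
                   cells$matrix, check.names = FALSE)
  colnames(df)[-(1:2)] <- channel_colnames(ncol(cells$matrix))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(FORMAT_HEADER, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cell_spectra
#' @export
read_cell_spectra <- function(path) {
  skip <- if (check_format_version(path)) 1 else 0
  df <- utils::read.csv(path, skip = skip, check.names = FALSE)
  required <- c("cell_id", "truth_label")
  if (!all(required %in% colnames(df)))
    stop(sprintf("%s: missing required column(s) %s", path,
                 paste(setdiff(required, colnames(df)), collapse = ", ")))
  ch <- grep("^ch[0-9]+$", colnames(df), value = TRUE)
  if (!length(ch)) stop(sprintf("%s: no channel columns (ch001..)", path))
  truth <- as.character(df$truth_label)
  if (all(is.na(truth) | truth == "")) truth <- NULL
  cell_spectra(df$cell_id, as.matrix(df[, ch, drop = FALSE]),
               truth_labels = truth, source = path)
}
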