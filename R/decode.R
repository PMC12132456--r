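#' Classify cells by maximum cosine similarity
#'
#' For every cell, the cosine similarity between its spectrum and each
#' candidate reference spectrum is computed; the cell is assigned the FP
#' with the maximum cosine similarity (MCS). Cells with zero-norm spectra
#' cannot be compared and are labelled \code{"unclassified"} rather than
#' dropped, so cell counts always reconcile. Exact ties at the maximum are
#' resolved to the first candidate in library order and flagged ambiguous.
#'
#' @param cells A \code{\link{cell_spectra}} matrix.
#' @param library A \code{\link{reference_library}}.
#' @param candidates Optional character vector restricting the candidate FP
#'   set (default: every FP in the library, in library order).
#' @param min_mcs Optional rejection threshold: cells whose MCS falls below
#'   it are labelled \code{"unclassified"}. \code{NULL} (default) classifies
#'   every cell, however poor the best match.
#' @return An object of class \code{classification_result} with fields
#'   \code{cell_ids}, \code{predicted_fp}, \code{mcs_value},
#'   \code{similarity_table} (n_cells x n_candidates), \code{ambiguous},
#'   \code{candidates}, and \code{truth_labels} carried over from
#'   \code{cells} when present.
#' @export
classify_cells <- function(cells, library, candidates = NULL, min_mcs = NULL) {
  stopifnot(inherits(cells, "cell_spectra"),
            inherits(library, "reference_library"))
  all_names <- fp_names(library)
  if (is.null(candidates)) candidates <- all_names
  if (!length(candidates)) stop("candidate set is empty")
  missing <- setdiff(candidates, all_names)
  if (length(missing))
    stop(sprintf("candidate FP(s) not in library: %s",
                 paste(missing, collapse = ", ")))
  refs <- library_matrix(library)[candidates, , drop = FALSE]
  if (ncol(refs) != ncol(cells$matrix))
    stop("cells and library have different channel counts")
  ref_norms <- sqrt(rowSums(refs * refs))
  if (any(ref_norms == 0))
    stop(sprintf("zero-norm reference spectrum: %s",
                 paste(candidates[ref_norms == 0], collapse = ", ")))
  cell_norms <- sqrt(rowSums(cells$matrix^2))
  sim <- cells$matrix %*% t(refs) / outer(pmax(cell_norms, .Machine$double.xmin),
                                          ref_norms)
  sim <- pmin(pmax(sim, 0), 1)
  colnames(sim) <- candidates
  rownames(sim) <- NULL
  best <- max.col(sim, ties.method = "first")
  mcs <- sim[cbind(seq_len(nrow(sim)), best)]
  n_at_max <- rowSums(sim == mcs)
  predicted <- candidates[best]
  ambiguous <- n_at_max > 1
  zero <- cell_norms == 0
  predicted[zero] <- "unclassified"
  mcs[zero] <- NA_real_
  sim[zero, ] <- NA_real_
  ambiguous[zero] <- FALSE
  if (!is.null(min_mcs)) {
    reject <- !zero & mcs < min_mcs
    predicted[reject] <- "unclassified"
  }
  structure(list(cell_ids = cells$cell_ids,
                 predicted_fp = predicted,
                 mcs_value = mcs,
                 similarity_table = sim,
                 ambiguous = ambiguous,
                 candidates = candidates,
                 truth_labels = cells$truth_labels),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("Classification: %d cells, %d candidate FPs\n",
              length(x$cell_ids), length(x$candidates)))
  print(table(x$predicted_fp))
  invisible(x)
}

#' Monoculture error rate
#'
#' In a monoculture every cell's true FP is known, so accuracy is
#' \deqn{Error rate = \#cells misclassified / total cells \times 100.}
#' Unclassified cells count as misclassified (the conservative choice).
#'
#' @param result A \code{\link{classify_cells}} result.
#' @param truth The FP actually expressed; must be among the candidates.
#' @return Percentage in [0, 100].
#' @export
error_rate <- function(result, truth) {
  stopifnot(inherits(result, "classification_result"))
  if (!length(result$cell_ids)) stop("empty classification result")
  if (!truth %in% result$candidates)
    stop(sprintf("truth FP '%s' was not among the candidates", truth))
  100 * sum(result$predicted_fp != truth) / length(result$predicted_fp)
}

#' FP-minus-one false-positive rate
#'
#' In an FP-minus-one (FpMO) co-culture one FP is omitted from the culture
#' while the decoder still offers it as a candidate; the ground truth is
#' that zero cells express it, so every call of the missing FP is a false
#' positive:
#' \deqn{\%FalsePositive = \#cells classified as missing FP / total cells
#'   \times 100.}
#'
#' @param result A \code{\link{classify_cells}} result.
#' @param missing_fp The FP omitted from the culture; must have been among
#'   the candidates.
#' @return Percentage in [0, 100].
#' @export
false_positive_rate <- function(result, missing_fp) {
  stopifnot(inherits(result, "classification_result"))
  if (!missing_fp %in% result$candidates)
    stop(sprintf("missing FP '%s' was not among the candidates", missing_fp))
  100 * sum(result$predicted_fp == missing_fp) / length(result$predicted_fp)
}

#' Stratify cells by radiance
#'
#' Ranks cells by radiance and splits them into equal-count strata (tertiles
#' by default: low / medium / high). Rank order rather than value thresholds
#' is used so duplicated radiances still split; when the cell count is not
#' divisible by \code{n_strata}, the remainder goes to the lower strata.
#'
#' @param cells A \code{\link{cell_spectra}} matrix.
#' @param n_strata Number of intensity groups (default 3).
#' @return Factor of length n_cells with levels \code{low < medium < high}
#'   for 3 strata, or \code{stratum_1 < ... < stratum_k} otherwise, aligned
#'   with \code{cells$cell_ids}.
#' @export
stratify_by_intensity <- function(cells, n_strata = 3L) {
  stopifnot(inherits(cells, "cell_spectra"))
  n <- n_cells(cells)
  if (n < n_strata) stop("fewer cells than strata")
  lev <- if (n_strata == 3) c("low", "medium", "high")
         else sprintf("stratum_%d", seq_len(n_strata))
  base_size <- n %/% n_strata
  rem <- n %% n_strata
  sizes <- rep(base_size, n_strata) + c(rep(1L, rem), rep(0L, n_strata - rem))
  stratum_of_rank <- rep(seq_len(n_strata), times = sizes)
  ranks <- rank(radiance(cells$matrix), ties.method = "first")
  factor(lev[stratum_of_rank[ranks]], levels = lev, ordered = TRUE)
}

#' Summarise a classification result
#'
#' @param object A \code{classification_result}.
#' @param truth Optional monoculture truth FP (adds \code{error_rate}).
#' @param missing_fp Optional FpMO missing FP (adds
#'   \code{false_positive_rate}).
#' @param ... Unused.
#' @return A list with per-FP counts and the requested rates (percentages).
#' @export
summary.classification_result <- function(object, truth = NULL,
                                          missing_fp = NULL, ...) {
  counts <- table(factor(object$predicted_fp,
                         levels = c(object$candidates, "unclassified")))
  out <- list(n_cells = length(object$cell_ids),
              counts = as.list(as.integer(counts)))
  names(out$counts) <- names(counts)
  if (!is.null(truth)) out$error_rate <- error_rate(object, truth)
  if (!is.null(missing_fp))
    out$false_positive_rate <- false_positive_rate(object, missing_fp)
  out
}

#' Write a classification result as CSV (+ optional JSON summary)
#'
#' CSV columns: \code{cell_id,predicted_fp,mcs,ambiguous} plus
#' \code{truth_label} when ground truth is known.
#'
#' @param result A \code{classification_result}.
#' @param path Output CSV path.
#' @param summary_path Optional JSON path for the
#'   \code{\link{summary.classification_result}} output.
#' @param truth,missing_fp Passed to the summary when given.
#' @return \code{path}, invisibly.
#' @export
write_classification <- function(result, path, summary_path = NULL,
                                 truth = NULL, missing_fp = NULL) {
  stopifnot(inherits(result, "classification_result"))
  df <- data.frame(cell_id = result$cell_ids,
                   predicted_fp = result$predicted_fp,
                   mcs = result$mcs_value,
                   ambiguous = result$ambiguous)
  if (!is.null(result$truth_labels)) df$truth_label <- result$truth_labels
  con <- file(path, "w")
  writeLines(FORMAT_HEADER, con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  if (!is.null(summary_path)) {
    s <- summary(result, truth = truth, missing_fp = missing_fp)
    jsonlite::write_json(s, summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read a classification result CSV
#'
#' Restores the row-level fields of \code{\link{write_classification}}
#' (\code{similarity_table} is not stored and comes back \code{NULL}).
#'
#' @param path CSV path.
#' @return A \code{classification_result}.
#' @export
read_classification <- function(path) {
  skip <- if (check_format_version(path)) 1 else 0
  df <- utils::read.csv(path, skip = skip)
  need <- c("cell_id", "predicted_fp", "mcs", "ambiguous")
  if (!all(need %in% colnames(df)))
    stop(sprintf("%s: expected columns %s", path, paste(need, collapse = ",")))
  structure(list(cell_ids = as.integer(df$cell_id),
                 predicted_fp = as.character(df$predicted_fp),
                 mcs_value = df$mcs,
                 similarity_table = NULL,
                 ambiguous = as.logical(df$ambiguous),
                 candidates = setdiff(unique(df$predicted_fp), "unclassified"),
                 truth_labels = if ("truth_label" %in% colnames(df))
                   as.character(df$truth_label) else NULL),
            class = "classification_result")
}
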