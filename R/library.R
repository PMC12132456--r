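#' Reference spectrum of one fluorescent protein
#'
#' The decoding codebook entry for an FP: the channel-wise average of all
#' cells in a monoculture. References are stored unnormalised; cosine
#' similarity is scale-invariant, so only spectral shape matters.
#'
#' @param fp_name FP name.
#' @param spectrum Numeric channel vector.
#' @param n_cells Number of cells averaged.
#' @param dim Dim-FP flag (see \code{\link{detect_dim_groups}}).
#' @return An object of class \code{reference_spectrum}.
#' @export
reference_spectrum <- function(fp_name, spectrum, n_cells = 1L, dim = FALSE) {
  stopifnot(is.character(fp_name), length(fp_name) == 1, n_cells >= 1)
  structure(list(fp_name = fp_name, spectrum = as.numeric(spectrum),
                 n_cells = as.integer(n_cells), dim = isTRUE(dim)),
            class = "reference_spectrum")
}

#' Build a reference spectrum from a monoculture
#'
#' Channel-wise mean of the per-cell mean intensities. Cells with zero
#' radiance carry no spectral shape and are excluded with a warning.
#'
#' @param cells A \code{\link{cell_spectra}} matrix from a monoculture.
#' @param fp_name Name of the FP expressed by the monoculture.
#' @return A \code{\link{reference_spectrum}}.
#' @export
build_reference <- function(cells, fp_name) {
  stopifnot(inherits(cells, "cell_spectra"))
  if (n_cells(cells) < 1) stop("empty cell matrix")
  r <- radiance(cells$matrix)
  keep <- r > 0
  if (!any(keep)) stop("all cells have zero radiance")
  if (any(!keep))
    warning(sprintf("excluding %d zero-radiance cell(s) from the %s reference",
                    sum(!keep), fp_name))
  m <- cells$matrix[keep, , drop = FALSE]
  reference_spectrum(fp_name, colMeans(m), n_cells = nrow(m))
}

#' Reference library
#'
#' An ordered, uniquely named collection of reference spectra sharing one
#' acquisition scheme — the codebook against which cells are classified.
#'
#' @param references List of \code{\link{reference_spectrum}} objects.
#' @param scheme The shared \code{\link{acquisition_scheme}}.
#' @return An object of class \code{reference_library}.
#' @export
reference_library <- function(references, scheme = default_scheme()) {
  stopifnot(all(vapply(references, inherits, TRUE, "reference_spectrum")),
            inherits(scheme, "acquisition_scheme"))
  nms <- vapply(references, `[[`, "", "fp_name")
  if (anyDuplicated(nms)) stop("duplicate fp_name in library")
  lens <- vapply(references, function(r) length(r$spectrum), 1L)
  if (any(lens != scheme$total_channels))
    stop(sprintf("reference spectra must have %d channels",
                 scheme$total_channels))
  names(references) <- nms
  structure(list(references = references, scheme = scheme),
            class = "reference_library")
}

#' @export
print.reference_library <- function(x, ...) {
  cat(sprintf("Reference library: %d FPs, %d channels\n",
              length(x$references), x$scheme$total_channels))
  for (r in x$references)
    cat(sprintf("  %s (%d cells%s)\n", r$fp_name, r$n_cells,
                if (r$dim) ", dim" else ""))
  invisible(x)
}

#' FP names of a library
#' @param library A \code{reference_library}.
#' @return Character vector in library order.
#' @export
fp_names <- function(library) {
  stopifnot(inherits(library, "reference_library"))
  names(library$references)
}

#' Reference spectra as a matrix
#' @param library A \code{reference_library}.
#' @return A n_fps x n_channels matrix with FP names as row names.
#' @export
library_matrix <- function(library) {
  stopifnot(inherits(library, "reference_library"))
  m <- do.call(rbind, lapply(library$references, `[[`, "spectrum"))
  rownames(m) <- fp_names(library)
  m
}

#' Per-cell log10 radiance distribution of a monoculture
#'
#' Radiance (the summed mean pixel intensity across all channels) is
#' computed per cell and base-10 log transformed, so brightness
#' distributions of different FPs can be compared on one scale.
#' Zero-radiance cells are dropped with a message reporting the count.
#'
#' @param cells A \code{\link{cell_spectra}} matrix.
#' @return Numeric vector of log10 radiance values, one per retained cell.
#' @export
radiance_distribution <- function(cells) {
  stopifnot(inherits(cells, "cell_spectra"))
  r <- radiance(cells$matrix)
  dropped <- sum(r == 0)
  if (dropped == length(r)) stop("all cells have zero radiance")
  if (dropped > 0)
    message(sprintf("dropped %d zero-radiance cell(s)", dropped))
  log10(r[r > 0])
}

#' Empirical 1-D Wasserstein-1 distance
#'
#' The earth-mover distance between two empirical distributions with equal
#' per-sample weight: the integral of the absolute difference between their
#' empirical CDFs, computed exactly from the pooled order statistics.
#'
#' @param x,y Numeric samples (any lengths >= 1).
#' @return Non-negative distance; 0 iff the empirical distributions match.
#' @export
wasserstein1 <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  all_v <- sort(c(x, y))
  if (length(all_v) == 1) return(0)
  deltas <- diff(all_v)
  grid <- all_v[-length(all_v)]
  cdf_x <- stats::ecdf(x)(grid)
  cdf_y <- stats::ecdf(y)(grid)
  sum(abs(cdf_x - cdf_y) * deltas)
}

#' Flag dim FPs by clustering radiance distributions
#'
#' Computes pairwise Wasserstein-1 distances between the per-FP log10
#' radiance distributions, clusters them by average-linkage hierarchical
#' clustering, cuts the tree at \code{n_groups}, and flags the cluster with
#' the lowest mean log10 radiance as dim. Dim FPs are poor decoding
#' candidates: their signal sits orders of magnitude below the rest of the
#' library.
#'
#' @param distributions Named list, FP name -> numeric log10 radiance values
#'   (each of length >= 2), e.g. from \code{\link{radiance_distribution}}.
#' @param n_groups Number of clusters to cut at (default 2: dim vs bright).
#' @return A data.frame with columns \code{fp_name}, \code{group},
#'   \code{mean_log10_radiance}, \code{dim}.
#' @export
detect_dim_groups <- function(distributions, n_groups = 2L) {
  if (length(distributions) < 2) stop("need at least 2 FPs")
  if (length(distributions) < n_groups)
    stop("fewer FPs than requested groups")
  if (any(lengths(distributions) < 2))
    stop("each FP needs at least 2 cells")
  nms <- names(distributions)
  k <- length(nms)
  d <- matrix(0, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    d[i, j] <- d[j, i] <- wasserstein1(distributions[[i]], distributions[[j]])
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  groups <- stats::cutree(hc, k = n_groups)
  means <- vapply(distributions, mean, 0)
  group_means <- tapply(means, groups, mean)
  dim_group <- as.integer(names(group_means)[which.min(group_means)])
  data.frame(fp_name = nms, group = as.integer(groups),
             mean_log10_radiance = unname(means),
             dim = as.integer(groups) == dim_group,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read / write a reference library as CSV
#'
#' Schema: \code{# specdex-format v1} comment, then
#' \code{fp_name,n_cells,dim,ch001..chNNN}; round-trips losslessly.
#'
#' @param library A \code{\link{reference_library}} (for writing).
#' @param path CSV file path.
#' @param scheme Scheme to attach when reading (default
#'   \code{\link{default_scheme}}).
#' @param normalized Write unit-norm spectra instead of raw means (for
#'   plotting exports; classification is unaffected either way).
#' @return \code{read_reference_library} returns a \code{reference_library}.
#' @export
write_reference_library <- function(library, path, normalized = FALSE) {
  stopifnot(inherits(library, "reference_library"))
  m <- library_matrix(library)
  if (normalized) m <- t(apply(m, 1, normalize_spectrum))
  df <- data.frame(fp_name = fp_names(library),
                   n_cells = vapply(library$references, `[[`, 1L, "n_cells"),
                   dim = vapply(library$references, `[[`, TRUE, "dim"),
                   m, check.names = FALSE)
  colnames(df)[-(1:3)] <- channel_colnames(ncol(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(FORMAT_HEADER, con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reference_library
#' @export
read_reference_library <- function(path, scheme = default_scheme()) {
  skip <- if (check_format_version(path)) 1 else 0
  df <- utils::read.csv(path, skip = skip, check.names = FALSE)
  if (!all(c("fp_name", "n_cells", "dim") %in% colnames(df)))
    stop(sprintf("%s: expected columns fp_name,n_cells,dim,ch001..", path))
  ch <- grep("^ch[0-9]+$", colnames(df), value = TRUE)
  refs <- lapply(seq_len(nrow(df)), function(i) {
    reference_spectrum(df$fp_name[i], as.numeric(df[i, ch]),
                       n_cells = df$n_cells[i], dim = as.logical(df$dim[i]))
  })
  reference_library(refs, scheme)
}
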