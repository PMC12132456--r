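#' Cosine similarity between two spectra
#'
#' The similarity of two non-negative emission spectra treated as vectors:
#' the dot product divided by the product of the Euclidean norms,
#' \deqn{CS(a, b) = \frac{\sum_{ch} a_{ch} b_{ch}}
#'   {\sqrt{\sum_{ch} a_{ch}^2} \sqrt{\sum_{ch} b_{ch}^2}}.}
#' The normalisation makes the score depend on spectral shape only, not on
#' absolute intensity: 1 means the spectra are positive scalar multiples of
#' each other, 0 means their non-zero channels do not overlap (orthogonality).
#' For non-negative spectra the score always lies in [0, 1].
#'
#' @param a,b Numeric vectors of equal length with non-negative entries and
#'   non-zero Euclidean norm.
#' @return A single similarity score in [0, 1].
#' @examples
#' s <- c(3, 4, rep(0, 98))
#' cosine_similarity(s, 2 * s)                 # 1
#' cosine_similarity(s, c(4, 3, rep(0, 98)))   # 0.96
#' @export
cosine_similarity <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b))
    stop(sprintf("spectra have different lengths (%d vs %d)",
                 length(a), length(b)))
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0)
    stop("cosine similarity is undefined for a zero-norm spectrum")
  s <- sum(a * b) / (na * nb)
  # clamp float overshoot; spectra are non-negative so the true value is in [0,1]
  min(max(s, 0), 1)
}

#' Pairwise cosine-similarity matrix
#'
#' @param spectra A list of numeric spectra (equal lengths, all non-zero), or
#'   a numeric matrix with one spectrum per row. Names (list names or row
#'   names) are carried to the output dimnames.
#' @return A symmetric matrix with unit diagonal and entries in [0, 1],
#'   rows/columns in input order.
#' @export
pairwise_similarity_matrix <- function(spectra) {
  if (is.matrix(spectra)) {
    m <- spectra
    nms <- rownames(m)
  } else {
    if (length(spectra) < 2) stop("need at least 2 spectra")
    lens <- lengths(spectra)
    if (length(unique(lens)) != 1) stop("spectra have differing lengths")
    m <- do.call(rbind, lapply(spectra, as.numeric))
    nms <- names(spectra)
  }
  if (nrow(m) < 2) stop("need at least 2 spectra")
  norms <- sqrt(rowSums(m * m))
  zero <- which(norms == 0)
  if (length(zero))
    stop(sprintf("zero-norm spectrum at position(s) %s",
                 paste(zero, collapse = ", ")))
  s <- (m %*% t(m)) / outer(norms, norms)
  s <- pmin(pmax(s, 0), 1)
  diag(s) <- 1
  dimnames(s) <- if (is.null(nms)) NULL else list(nms, nms)
  s
}

#' Per-cell radiance
#'
#' Radiance is the summed mean pixel intensity across all channels of a
#' spectrum — the integrated brightness used for dim-FP detection and
#' intensity stratification. \code{log10_radiance} applies the base-10 log
#' and errors when the radiance is zero.
#'
#' @param s Numeric spectrum (or matrix with one spectrum per row, in which
#'   case a per-row vector is returned).
#' @return Non-negative scalar (or vector for matrix input).
#' @export
radiance <- function(s) {
  if (is.matrix(s)) rowSums(s) else sum(as.numeric(s))
}

#' @rdname radiance
#' @export
log10_radiance <- function(s) {
  r <- radiance(s)
  if (any(r == 0))
    stop("log10 radiance is undefined for zero-radiance spectra")
  log10(r)
}

#' Normalise a spectrum to unit Euclidean norm
#'
#' Cosine similarity already normalises internally, so decoding never needs
#' this; it exists for plotting spectra on a common scale.
#'
#' @param s Numeric spectrum with non-zero norm.
#' @return The spectrum scaled to Euclidean norm 1.
#' @export
normalize_spectrum <- function(s) {
  s <- as.numeric(s)
  n <- sqrt(sum(s * s))
  if (n == 0) stop("cannot normalize a zero-norm spectrum")
  s / n
}
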