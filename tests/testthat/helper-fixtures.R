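# Shared fixtures, built in code.

# random non-negative spectrum of length n (at least one positive entry)
rand_spectrum <- function(n = 100) {
  s <- stats::runif(n)
  s[s < 0.2] <- 0
  if (all(s == 0)) s[1] <- 1
  s
}

# a small well-separated library built from the synthetic panel
toy_library <- function(n_fps = 3) {
  panel <- default_fp_panel(n_fps)
  refs <- lapply(panel, function(fp)
    reference_spectrum(fp$name, model_spectrum(fp, default_scheme())))
  reference_library(refs)
}

# cell_spectra whose rows are exactly the library's reference spectra
library_as_cells <- function(lib) {
  m <- library_matrix(lib)
  cell_spectra(seq_len(nrow(m)), m, truth_labels = rownames(m),
               source = "library_as_cells")
}

# random symmetric similarity matrix with unit diagonal, from random spectra
rand_similarity_matrix <- function(k, n = 20) {
  m <- t(vapply(seq_len(k), function(i) rand_spectrum(n), numeric(n)))
  rownames(m) <- sprintf("FP%02d", seq_len(k))
  pairwise_similarity_matrix(m)
}

# brute-force palette oracle: all C(k, n) subsets, filtered and sorted the
# same way the enumerator sorts (ascending objective, then lexicographic)
brute_force_tuples <- function(matrix, n, threshold = 0.9, strict = TRUE,
                               include = character(), exclude = character()) {
  nms <- rownames(matrix)
  pool <- setdiff(nms, exclude)
  combos <- utils::combn(pool, n, simplify = FALSE)
  combos <- Filter(function(s) all(include %in% s), combos)
  keep <- Filter(function(s) {
    sub <- matrix[s, s]
    off <- sub[upper.tri(sub)]
    if (strict) all(off < threshold) else all(off <= threshold)
  }, combos)
  obj <- vapply(keep, function(s) {
    sub <- matrix[s, s]
    sum(sub[upper.tri(sub)])
  }, 0)
  key <- vapply(keep, function(s) paste(sort(s), collapse = "\r"), "")
  keep[order(obj, key)]
}
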