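test_that("green-panel fixture admits exactly 8 3-tuples and no 4-tuples", {
  m <- green_panel_matrix()
  expect_equal(dim(m), c(7, 7))
  expect_equal(m, t(m))
  sols3 <- enumerate_feasible_tuples(m, palette_query(3))
  expect_length(sols3, 8)
  # every feasible triple takes at most one FP per spectral pattern
  for (s in sols3) {
    expect_true("mT-Sapphire" %in% s$fp_names)
    expect_lte(sum(s$fp_names %in% c("EGFP", "mUkG", "mAvicFP1", "Clover")), 1)
    expect_lte(sum(s$fp_names %in% c("mNeonGreen", "mClover3")), 1)
  }
  for (n in 4:7)
    expect_length(enumerate_feasible_tuples(m, palette_query(n)), 0)
})

test_that("identity matrix yields all C(k, n) subsets", {
  m <- diag(4)
  dimnames(m) <- list(LETTERS[1:4], LETTERS[1:4])
  expect_length(enumerate_feasible_tuples(m, palette_query(2)), 6)
  expect_length(enumerate_feasible_tuples(m, palette_query(4)), 1)
})

test_that("enumeration equals brute force on random matrices", {
  set.seed(31)
  for (trial in 1:30) {
    k <- sample(5:10, 1)
    m <- rand_similarity_matrix(k)
    n <- sample(2:4, 1)
    thr <- stats::runif(1, 0.3, 0.95)
    sols <- enumerate_feasible_tuples(m, palette_query(n, threshold = thr))
    oracle <- brute_force_tuples(m, n, threshold = thr)
    expect_equal(lapply(sols, `[[`, "fp_names"), oracle)
  }
})

test_that("every solution is feasible, sorted, with exact objectives", {
  set.seed(37)
  m <- rand_similarity_matrix(9)
  sols <- enumerate_feasible_tuples(m, palette_query(3, threshold = 0.8))
  expect_gt(length(sols), 0)
  objs <- vapply(sols, `[[`, 0, "objective")
  expect_true(all(diff(objs) >= -1e-15))
  for (s in sols) {
    expect_true(s$feasible)
    off <- s$submatrix[upper.tri(s$submatrix)]
    expect_true(all(off < 0.8))
    expect_identical(s$objective, sum(off))
    expect_equal(s$submatrix, m[s$fp_names, s$fp_names])
  }
})

test_that("threshold raises monotonically and feasibility nests", {
  set.seed(41)
  m <- rand_similarity_matrix(8)
  get_names <- function(n, thr) {
    vapply(enumerate_feasible_tuples(m, palette_query(n, threshold = thr)),
           function(s) paste(sort(s$fp_names), collapse = "|"), "")
  }
  lo <- get_names(3, 0.5); mid <- get_names(3, 0.7); hi <- get_names(3, 0.9)
  expect_true(all(lo %in% mid))
  expect_true(all(mid %in% hi))
  # any feasible 4-tuple implies all its 3-sub-tuples feasible
  four <- enumerate_feasible_tuples(m, palette_query(4, threshold = 0.8))
  three <- get_names(3, 0.8)
  for (s in four) {
    subs <- utils::combn(s$fp_names, 3, function(x)
      paste(sort(x), collapse = "|"))
    expect_true(all(subs %in% three))
  }
})

test_that("include/exclude constraints are honoured", {
  m <- green_panel_matrix()
  inc <- enumerate_feasible_tuples(m, palette_query(3, include = "EGFP"))
  expect_length(inc, 2)   # EGFP + mT-Sapphire + one of the pattern-2 pair
  expect_true(all(vapply(inc, function(s) "EGFP" %in% s$fp_names, TRUE)))
  exc <- enumerate_feasible_tuples(m,
    palette_query(3, exclude = "mT-Sapphire"))
  expect_length(exc, 0)   # sapphire is in every feasible triple
  expect_error(enumerate_feasible_tuples(m, palette_query(3, include = "zz")),
               "not in matrix")
  expect_error(palette_query(3, include = "A", exclude = "A"), "overlap")
  # include an FP conflicting with everything -> no pairs at all
  conflicted <- matrix(0.99, 3, 3, dimnames = list(c("A", "B", "C"),
                                                   c("A", "B", "C")))
  diag(conflicted) <- 1
  expect_length(enumerate_feasible_tuples(conflicted,
    palette_query(2, include = "A")), 0)
})

test_that("optimal_ntuple is the minimum-sum feasible tuple", {
  set.seed(43)
  for (trial in 1:10) {
    m <- rand_similarity_matrix(8)
    best <- optimal_ntuple(m, palette_query(3, threshold = 0.9))
    oracle <- brute_force_tuples(m, 3, threshold = 0.9)
    if (is.null(best)) expect_length(oracle, 0)
    else expect_equal(best$fp_names, oracle[[1]])
  }
  m <- green_panel_matrix()
  full <- optimal_ntuple(diag(3) |>
    `dimnames<-`(list(c("A", "B", "C"), c("A", "B", "C"))),
    palette_query(3))
  expect_equal(full$fp_names, c("A", "B", "C"))
})

test_that("strict vs inclusive threshold differ only at the boundary", {
  nms <- c("A", "B", "C")
  m <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.1, 0.1, 0.1, 1), 3, 3,
              dimnames = list(nms, nms))
  strict <- enumerate_feasible_tuples(m, palette_query(2, strict = TRUE))
  loose <- enumerate_feasible_tuples(m, palette_query(2, strict = FALSE))
  expect_length(strict, 2)   # AB excluded at exactly 0.9
  expect_length(loose, 3)
})

test_that("dedupe keeps one representative per conflict component", {
  m <- green_panel_matrix()
  red <- dedupe_prefilter(m, 0.9)
  # pattern 1 collapses to EGFP, pattern 2 to mNeonGreen
  expect_setequal(rownames(red), c("EGFP", "mNeonGreen", "mT-Sapphire"))
  ident <- diag(3)
  dimnames(ident) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(dedupe_prefilter(ident, 0.9), ident)
  # chain A~B, B~C is one component -> single representative A
  nms <- c("A", "B", "C")
  chain <- matrix(c(1, 0.95, 0.1, 0.95, 1, 0.95, 0.1, 0.95, 1), 3, 3,
                  dimnames = list(nms, nms))
  expect_equal(rownames(dedupe_prefilter(chain, 0.9)), "A")
})

test_that("max_results truncates the sorted list with a flag", {
  m <- diag(6)
  dimnames(m) <- list(LETTERS[1:6], LETTERS[1:6])
  q <- palette_query(2, max_results = 5)
  sols <- enumerate_feasible_tuples(m, q)
  expect_length(sols, 5)
  expect_true(attr(sols, "truncated"))
  all15 <- enumerate_feasible_tuples(m, palette_query(2))
  expect_false(attr(all15, "truncated"))
  expect_length(all15, 15)
})

test_that("palette report writes heatmap, spectra and JSON that round-trips", {
  lib <- toy_library(3)
  m <- pairwise_similarity_matrix(library_matrix(lib))
  sol <- optimal_ntuple(m, palette_query(3))
  dir <- withr::local_tempdir()
  paths <- export_palette_report(sol, lib, dir)
  expect_true(all(file.exists(paths)))
  back <- jsonlite::fromJSON(paths[["json"]])
  expect_equal(back$fp_names, sol$fp_names)
  expect_equal(back$objective, sol$objective)
  expect_equal(back$submatrix, unname(sol$submatrix), tolerance = 1e-12)
  bad <- palette_solution("ghost", matrix(1, 1, 1))
  expect_error(export_palette_report(bad, lib, dir), "not in library")
})
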