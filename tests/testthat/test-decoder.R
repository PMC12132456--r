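test_that("a library classifies itself perfectly", {
  lib <- toy_library(5)
  cells <- library_as_cells(lib)
  res <- classify_cells(cells, lib)
  expect_equal(res$predicted_fp, fp_names(lib))
  expect_equal(unname(res$mcs_value), rep(1, 5), tolerance = 1e-12)
  expect_false(any(res$ambiguous))
  for (nm in fp_names(lib)) {
    sub <- classify_cells(cells, lib, candidates = nm)
    expect_true(all(sub$predicted_fp == nm))   # single candidate takes all
  }
  expect_equal(error_rate(res, "sGreen"), 80)  # 4 of 5 cells are not sGreen
})

test_that("mcs equals the row maximum and the table matches the kernel", {
  set.seed(17)
  lib <- toy_library(4)
  cells <- cell_spectra(1:6, t(vapply(1:6, function(i) rand_spectrum(100),
                                      numeric(100))))
  res <- classify_cells(cells, lib)
  refs <- library_matrix(lib)
  for (i in 1:6) {
    for (nm in fp_names(lib))
      expect_equal(unname(res$similarity_table[i, nm]),
                   cosine_similarity(cells$matrix[i, ], refs[nm, ]),
                   tolerance = 1e-12)
    expect_equal(res$mcs_value[i], max(res$similarity_table[i, ]))
    expect_equal(res$predicted_fp[i],
                 fp_names(lib)[which.max(res$similarity_table[i, ])])
  }
})

test_that("zero-norm cells are unclassified, ties flagged ambiguous", {
  lib <- reference_library(list(
    reference_spectrum("A", c(rep(1, 50), rep(0, 50))),
    reference_spectrum("B", c(rep(0, 50), rep(1, 50)))))
  m <- rbind(rep(0, 100),      # zero-norm
             rep(1, 100))      # equidistant from A and B
  res <- classify_cells(cell_spectra(1:2, m), lib)
  expect_equal(res$predicted_fp[1], "unclassified")
  expect_true(is.na(res$mcs_value[1]))
  expect_equal(res$predicted_fp[2], "A")   # first in library order
  expect_true(res$ambiguous[2])
  # unclassified counts as misclassified
  expect_equal(error_rate(res, "A"), 50)
})

test_that("error_rate reproduces printed-precision percentages", {
  lib <- toy_library(2)
  make_result <- function(n_wrong, n_total) {
    m <- library_matrix(lib)
    rows <- m[c(rep(2, n_wrong), rep(1, n_total - n_wrong)), ]
    classify_cells(cell_spectra(seq_len(n_total), rows), lib)
  }
  res <- make_result(32, 10000)
  expect_equal(error_rate(res, fp_names(lib)[1]), 0.32)
  expect_equal(error_rate(make_result(4774, 10000), fp_names(lib)[1]), 47.74)
  expect_equal(error_rate(make_result(0, 100), fp_names(lib)[1]), 0)
  # correctness complement is exact
  correct <- 100 * sum(res$predicted_fp == fp_names(lib)[1]) /
    length(res$predicted_fp)
  expect_identical(error_rate(res, fp_names(lib)[1]) + correct, 100)
  expect_error(error_rate(res, "nope"), "not among the candidates")
})

test_that("false_positive_rate counts calls of the missing FP", {
  lib <- toy_library(3)
  m <- library_matrix(lib)
  # 1000 cells: 999 split between FPs 1-2, one called as FP 3
  rows <- m[c(rep(1, 500), rep(2, 499), 3), ]
  res <- classify_cells(cell_spectra(1:1000, rows), lib)
  expect_equal(false_positive_rate(res, fp_names(lib)[3]), 0.1)
  expect_equal(false_positive_rate(res, fp_names(lib)[1]), 50)
  none <- classify_cells(cell_spectra(1:2, m[c(1, 2), ]), lib)
  expect_equal(false_positive_rate(none, fp_names(lib)[3]), 0)
  expect_error(false_positive_rate(res, "nope"), "not among the candidates")
})

test_that("classification is invariant to per-cell intensity scaling", {
  set.seed(19)
  lib <- toy_library(6)
  cells <- cell_spectra(1:20, t(vapply(1:20, function(i) rand_spectrum(100),
                                       numeric(100))))
  base <- classify_cells(cells, lib)$predicted_fp
  scales <- stats::runif(20, 0.01, 1000)
  scaled <- cell_spectra(1:20, cells$matrix * scales)
  expect_equal(classify_cells(scaled, lib)$predicted_fp, base)
})

test_that("restricting candidates keeps labels already in the subset", {
  set.seed(23)
  lib <- toy_library(6)
  cells <- cell_spectra(1:30, t(vapply(1:30, function(i) rand_spectrum(100),
                                       numeric(100))))
  full <- classify_cells(cells, lib)
  subset <- fp_names(lib)[1:3]
  res <- classify_cells(cells, lib, candidates = subset)
  expect_true(all(res$predicted_fp %in% subset))
  kept <- full$predicted_fp %in% subset
  expect_equal(res$predicted_fp[kept], full$predicted_fp[kept])
  expect_error(classify_cells(cells, lib, candidates = "ghost"),
               "not in library")
})

test_that("min_mcs rejection labels poor matches unclassified", {
  lib <- reference_library(list(
    reference_spectrum("A", c(rep(1, 50), rep(0, 50))),
    reference_spectrum("B", c(rep(0, 50), rep(1, 50)))))
  cells <- cell_spectra(1:2, rbind(c(rep(1, 50), rep(0, 50)), rep(1, 100)))
  res <- classify_cells(cells, lib, min_mcs = 0.9)
  expect_equal(res$predicted_fp, c("A", "unclassified"))
})

test_that("intensity strata are balanced, rank-ordered tertiles", {
  cells3 <- cell_spectra(1:3, rbind(rep(0.01, 100), rep(0.1, 100), rep(1, 100)))
  s <- stratify_by_intensity(cells3)
  expect_equal(as.character(s), c("low", "medium", "high"))
  cells6 <- cell_spectra(1:6, matrix(rep(1:6, each = 100), 6, 100,
                                     byrow = TRUE))
  expect_equal(as.vector(table(stratify_by_intensity(cells6))), c(2, 2, 2))
  # remainder goes to the lower strata: 7 cells -> 3/2/2
  cells7 <- cell_spectra(1:7, matrix(rep(1:7, each = 100), 7, 100,
                                     byrow = TRUE))
  expect_equal(as.vector(table(stratify_by_intensity(cells7))), c(3, 2, 2))
  # duplicated radiances still split by rank
  dup <- cell_spectra(1:6, matrix(1, 6, 100))
  expect_equal(as.vector(table(stratify_by_intensity(dup))), c(2, 2, 2))
  expect_error(stratify_by_intensity(cells3, 4), "fewer cells")
})

test_that("noisy low-intensity cells err at least as often as bright ones", {
  panel <- default_fp_panel(12)[c("sGreen", "sYellGrn")]  # hardest pair
  sch <- default_scheme()
  specs <- vapply(panel, model_spectrum, numeric(100), scheme = sch)
  lib <- reference_library(list(
    reference_spectrum("sGreen", specs[, 1]),
    reference_spectrum("sYellGrn", specs[, 2])))
  set.seed(29)
  n <- 300
  expr <- 10^stats::runif(n, 0.5, 2.5)    # wide intensity range
  m <- t(vapply(seq_len(n), function(i)
    pmax(expr[i] * specs[, 1] + stats::rnorm(100, sd = 4), 0),
    numeric(100)))
  cells <- cell_spectra(seq_len(n), m)
  res <- classify_cells(cells, lib)
  strata <- stratify_by_intensity(cells)
  err <- vapply(levels(strata), function(l)
    mean(res$predicted_fp[strata == l] != "sGreen"), 0)
  expect_gte(err[["low"]], err[["high"]])
})

test_that("classification CSV and JSON summary round-trip", {
  lib <- toy_library(3)
  cells <- library_as_cells(lib)
  res <- classify_cells(cells, lib)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_classification(res, csv, summary_path = js,
                       truth = fp_names(lib)[1])
  back <- read_classification(csv)
  expect_equal(back$predicted_fp, res$predicted_fp)
  expect_equal(back$mcs_value, unname(res$mcs_value), tolerance = 1e-9)
  s <- jsonlite::fromJSON(js)
  expect_equal(s$n_cells, 3)
  expect_equal(s$error_rate, error_rate(res, fp_names(lib)[1]))
})
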