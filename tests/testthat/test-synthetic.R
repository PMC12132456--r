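test_that("model spectra have block structure and sensible limits", {
  sch <- default_scheme()
  # emission far outside the detected range -> all-zero, flagged
  far <- synthetic_fp("uv", 300, 330)
  expect_warning(s <- model_spectrum(far, sch), "all-zero")
  expect_true(all(s == 0))
  # identical parameters -> identical shape
  a <- synthetic_fp("a", 488, 509)
  b <- synthetic_fp("b", 488, 509, brightness = 3)
  expect_equal(cosine_similarity(model_spectrum(a, sch),
                                 model_spectrum(b, sch)), 1)
  # a green/orange pair is well resolved
  egfp_like <- synthetic_fp("g", 488, 507)
  mko_like <- synthetic_fp("o", 548, 559)
  expect_lt(cosine_similarity(model_spectrum(egfp_like, sch),
                              model_spectrum(mko_like, sch)), 0.5)
  # notch guard zeroes channels at/below laser + 10 nm
  centers <- channel_centers(sch)
  s <- model_spectrum(egfp_like, sch)
  block3 <- 59:80
  expect_true(all(s[block3][centers[block3] < 498] == 0))
})

test_that("default panel is resolvable at 12 and crowded at 15", {
  sch <- default_scheme()
  expect_error(default_fp_panel(0))
  expect_error(default_fp_panel(16))
  expect_length(default_fp_panel(1), 1)
  m12 <- pairwise_similarity_matrix(
    lapply(default_fp_panel(12), model_spectrum, scheme = sch))
  expect_lt(max(m12[upper.tri(m12)]), 0.9)
  m15 <- pairwise_similarity_matrix(
    lapply(default_fp_panel(15), model_spectrum, scheme = sch))
  expect_gt(max(m15[upper.tri(m15)]), 0.9)
  pair <- confusable_fp_pair()
  expect_gt(cosine_similarity(model_spectrum(pair[[1]], sch),
                              model_spectrum(pair[[2]], sch)), 0.95)
})

test_that("scene simulation is a pure function of spec and seed", {
  panel <- default_fp_panel(2)
  cells <- data.frame(row = c(10, 25), col = c(10, 25), radius = 4,
                      fp_name = names(panel), expression = c(100, 200))
  sp <- scene_spec(c(40, 40), cells, seed = 5, poisson = TRUE)
  s1 <- simulate_scene(sp, panel)
  s2 <- simulate_scene(sp, panel)
  expect_identical(s1$stack$pixels, s2$stack$pixels)
  expect_identical(s1$mask$labels, s2$mask$labels)
  sp2 <- scene_spec(c(40, 40), cells, seed = 6, poisson = TRUE)
  expect_false(identical(simulate_scene(sp2, panel)$stack$pixels,
                         s1$stack$pixels))
})

test_that("scene generator validates cells and flags overlap", {
  panel <- default_fp_panel(1)
  out <- data.frame(row = 2, col = 20, radius = 5,
                    fp_name = "sSapphire", expression = 10)
  expect_error(scene_spec(c(40, 40), out, seed = 1), "outside")
  expect_error(scene_spec(c(40, 40), out[, 1:3], seed = 1), "columns")
  lap <- data.frame(row = c(20, 22), col = c(20, 22), radius = 4,
                    fp_name = "sSapphire", expression = 10)
  sp <- scene_spec(c(40, 40), lap, seed = 1, gaussian_sd = 0)
  expect_warning(simulate_scene(sp, panel), "overlapping")
  expect_error(simulate_scene(
    scene_spec(c(40, 40),
               data.frame(row = 20, col = 20, radius = 3,
                          fp_name = "ghost", expression = 1),
               seed = 1), panel), "undefined FP")
})

test_that("noise-free scenes round-trip through extraction exactly", {
  panel <- default_fp_panel(3)
  sch <- default_scheme()
  scene <- simulate_experiment("equal_mix", panel, n_cells = 9, seed = 4,
                               background_level = 0, gaussian_sd = 0)
  cells <- extract_cell_spectra(scene$stack, scene$mask,
                                truth_labels = scene$truth)
  for (i in seq_len(n_cells(cells)))
    expect_equal(cosine_similarity(
      cells$matrix[i, ],
      model_spectrum(panel[[cells$truth_labels[i]]], sch)), 1,
      tolerance = 1e-6)
})

test_that("experiment designs produce the stated truth compositions", {
  panel <- default_fp_panel(4)
  mono <- simulate_experiment("monoculture", panel, n_cells = 10, seed = 1,
                              fp = "sCyan")
  expect_true(all(mono$truth == "sCyan"))
  mix <- simulate_experiment("equal_mix", panel, n_cells = 200, seed = 2)
  expect_setequal(unique(mix$truth), names(panel))
  fpmo <- simulate_experiment("fpmo", panel, n_cells = 100, seed = 3,
                              missing_fp = "sTeal")
  expect_false("sTeal" %in% fpmo$truth)
  expect_setequal(unique(fpmo$truth), setdiff(names(panel), "sTeal"))
  expect_error(simulate_experiment("fpmo", panel, 10, 1,
                                   missing_fp = "ghost"), "not in panel")
})

test_that("clonal growth expands clones and dilutes expression", {
  panel <- default_fp_panel(2)
  days <- simulate_experiment("clonal_growth", panel, n_cells = 4, seed = 9,
                              days = 3, gaussian_sd = 0, background_level = 0)
  expect_length(days, 3)
  sizes <- vapply(days, function(d) length(d$truth), 1)
  expect_true(all(diff(sizes) > 0))           # clones grow day over day
  # each day's cells per founder: 1, 2, 4
  expect_equal(sizes, 4 * c(1, 2, 4))
  # expression dilution: day-3 cells are dimmer than day-1 founders
  r1 <- max(radiance(extract_cell_spectra(days[[1]]$stack,
                                          days[[1]]$mask)$matrix))
  r3 <- max(radiance(extract_cell_spectra(days[[3]]$stack,
                                          days[[3]]$mask)$matrix))
  expect_lt(r3, r1)
  expect_error(simulate_experiment("clonal_growth", panel, 2, 1, days = 1),
               "days >= 2")
})

test_that("misclassification grows with reference similarity under noise", {
  sch <- default_scheme()
  base <- synthetic_fp("base", 488, 509, 55, 36)
  partners <- list(synthetic_fp("far", 560, 590, 55, 40),
                   synthetic_fp("near", 505, 527, 55, 38),
                   synthetic_fp("twin", 490, 511, 55, 36))
  set.seed(77)
  err <- vapply(partners, function(p) {
    refs <- reference_library(list(
      reference_spectrum("base", model_spectrum(base, sch)),
      reference_spectrum("p", model_spectrum(p, sch))))
    truth_spec <- model_spectrum(base, sch)
    m <- t(vapply(1:150, function(i)
      pmax(8 * truth_spec + stats::rnorm(100, sd = 4), 0), numeric(100)))
    res <- classify_cells(cell_spectra(1:150, m), refs)
    mean(res$predicted_fp != "base")
  }, 0)
  sims <- vapply(partners, function(p)
    cosine_similarity(model_spectrum(base, sch), model_spectrum(p, sch)), 0)
  expect_true(all(diff(sims) > 0))     # partners ordered by similarity
  expect_true(all(diff(err) >= 0))     # error non-decreasing in similarity
  expect_gt(err[3], 0.1)               # confusable twin misclassifies often
})

test_that("end-to-end decoding is invariant to expression scaling", {
  panel <- default_fp_panel(3)
  scene <- simulate_experiment("equal_mix", panel, n_cells = 30, seed = 15)
  cells <- extract_cell_spectra(scene$stack, scene$mask)
  lib <- toy_library(3)
  base <- classify_cells(cells, lib)$predicted_fp
  scaled <- cell_spectra(cells$cell_ids, cells$matrix * 10)
  expect_equal(classify_cells(scaled, lib)$predicted_fp, base)
})
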