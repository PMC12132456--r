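#' Synthetic fluorescent protein
#'
#' A parametric FP model used by the scene simulator: Gaussian excitation
#' and emission bands (FWHM-parameterised) with a relative brightness.
#' Real FP spectra are asymmetric, but a smooth two-band model is enough to
#' produce realistic block-structured 100-channel spectra with controllable
#' pairwise overlap; measured spectra can be supplied through a reference
#' library CSV instead whenever shape fidelity matters.
#'
#' @param name FP name.
#' @param ex_max_nm,em_max_nm Excitation / emission maxima (nm);
#'   \code{em_max_nm >= ex_max_nm} (non-negative Stokes shift).
#' @param ex_fwhm_nm,em_fwhm_nm Full width at half maximum of the two bands
#'   (nm), both > 0.
#' @param brightness Relative brightness scalar > 0.
#' @return An object of class \code{synthetic_fp}.
#' @export
synthetic_fp <- function(name, ex_max_nm, em_max_nm,
                         ex_fwhm_nm = 60, em_fwhm_nm = 40, brightness = 1) {
  if (em_max_nm < ex_max_nm) stop("Stokes shift must be non-negative")
  if (ex_fwhm_nm <= 0 || em_fwhm_nm <= 0) stop("band widths must be positive")
  if (brightness <= 0) stop("brightness must be positive")
  structure(list(name = name, ex_max_nm = ex_max_nm, em_max_nm = em_max_nm,
                 ex_fwhm_nm = ex_fwhm_nm, em_fwhm_nm = em_fwhm_nm,
                 brightness = brightness),
            class = "synthetic_fp")
}

fwhm_to_sd <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Model 100-channel spectrum of a synthetic FP
#'
#' For each acquisition block, the per-channel intensity is
#' \code{brightness x (sum over the block's laser lines of the Gaussian
#' excitation efficiency at that laser) x (Gaussian emission density at the
#' channel centre)}, with channels whose centre lies below the block's
#' highest laser line + \code{notch_nm} zeroed — emulating the detector's
#' laser-exclusion notch. Blocks are concatenated in order, so one FP gives
#' a characteristically block-structured spectrum: the same emission shape
#' re-weighted by how well each block's lasers excite it.
#'
#' @param fp A \code{\link{synthetic_fp}}.
#' @param scheme An \code{\link{acquisition_scheme}}.
#' @param notch_nm Guard band above the highest laser line of each block
#'   (default 10 nm).
#' @return Numeric spectrum of length \code{scheme$total_channels}; a
#'   warning is raised when the spectrum is all-zero (the FP's emission
#'   falls outside the detected range and it cannot serve as a reference).
#' @export
model_spectrum <- function(fp, scheme, notch_nm = 10) {
  stopifnot(inherits(fp, "synthetic_fp"), inherits(scheme, "acquisition_scheme"))
  ex_sd <- fwhm_to_sd(fp$ex_fwhm_nm)
  em_sd <- fwhm_to_sd(fp$em_fwhm_nm)
  out <- unlist(lapply(scheme$blocks, function(b) {
    centers <- b$emission_start_nm +
      (seq_len(b$n_channels) - 0.5) * b$channel_width_nm
    exc <- sum(exp(-(b$laser_lines_nm - fp$ex_max_nm)^2 / (2 * ex_sd^2)))
    em <- exp(-(centers - fp$em_max_nm)^2 / (2 * em_sd^2))
    v <- fp$brightness * exc * em
    v[centers < max(b$laser_lines_nm) + notch_nm] <- 0
    v
  }), use.names = FALSE)
  # Gaussian tails never reach exact zero; treat intensities below 1e-6 of
  # the brightness scale as undetectable so out-of-range FPs are all-zero
  out[out < fp$brightness * 1e-6] <- 0
  if (all(out == 0))
    warning(sprintf("%s: model spectrum is all-zero under this scheme", fp$name))
  out
}

#' Default synthetic FP panel
#'
#' A fixed panel of up to 15 synthetic FPs whose excitation/emission maxima
#' span the detected range (420-695 nm), ordered by emission maximum. The
#' spacing was chosen so that, under the default acquisition scheme, all
#' pairwise model-spectrum cosine similarities of the first 12 panel members
#' stay below the 0.9 resolvability threshold — i.e. the panel is a valid
#' 12-plex palette by construction. Members 13-15 crowd the green-yellow
#' region and push some pairs above 0.9, exercising the infeasible regime.
#' The first panel member is a large-Stokes-shift violet-excited FP
#' (mT-Sapphire-like).
#'
#' @param n Number of FPs (1-15).
#' @return Named list of \code{\link{synthetic_fp}} objects.
#' @seealso \code{\link{confusable_fp_pair}} for a deliberately
#'   near-identical pair used in negative tests.
#' @export
default_fp_panel <- function(n) {
  if (n < 1 || n > 15) stop("panel size must be between 1 and 15")
  params <- list(
    #    name        ex   em   exw  emw
    list("sSapphire", 405, 512, 55, 40),   # large Stokes shift
    list("sBlue",     415, 447, 50, 35),
    list("sCyan",     442, 474, 55, 38),
    list("sTeal",     455, 488, 55, 38),
    list("sGreen",    488, 509, 55, 36),
    list("sYellGrn",  505, 527, 55, 38),
    list("sYellow",   514, 540, 55, 40),
    list("sOrange",   548, 562, 55, 40),
    list("sRedOrg",   561, 585, 55, 42),
    list("sRed",      574, 610, 60, 45),
    list("sCrimson",  600, 632, 60, 48),
    list("sFarRed",   620, 660, 60, 50),
    list("sGreen2",   492, 512, 55, 36),   # crowds sGreen
    list("sYellow2",  516, 543, 55, 40),   # crowds sYellow
    list("sOrange2",  550, 565, 55, 40)    # crowds sOrange
  )
  fps <- lapply(params[seq_len(n)], function(p)
    synthetic_fp(p[[1]], p[[2]], p[[3]], p[[4]], p[[5]]))
  names(fps) <- vapply(fps, `[[`, "", "name")
  fps
}

#' A deliberately confusable FP pair
#'
#' Two synthetic FPs with nearly identical bands (model-spectrum cosine
#' similarity > 0.95 under the default scheme), for negative tests of the
#' resolvability threshold: under noise, such a pair is mutually
#' misclassified at high rates.
#'
#' @return Named list of two \code{\link{synthetic_fp}} objects.
#' @export
confusable_fp_pair <- function() {
  fps <- list(sTwinA = synthetic_fp("sTwinA", 488, 507, 55, 36),
              sTwinB = synthetic_fp("sTwinB", 490, 510, 55, 36))
  fps
}

#' Scene description for the synthetic generator
#'
#' @param image_shape Integer c(rows, cols).
#' @param cells data.frame with columns \code{row}, \code{col},
#'   \code{radius}, \code{fp_name}, \code{expression}; every disc must lie
#'   fully inside the image.
#' @param background_level Constant background intensity (default 2).
#' @param gaussian_sd Additive Gaussian read-noise sd (default 3).
#' @param poisson Apply Poisson shot noise to the expected counts?
#' @param seed Mandatory RNG seed; scenes are pure functions of
#'   (spec, seed).
#' @return An object of class \code{scene_spec}.
#' @export
scene_spec <- function(image_shape, cells, background_level = 2,
                       gaussian_sd = 3, poisson = FALSE, seed) {
  if (missing(seed)) stop("a seed is required")
  cells <- as.data.frame(cells)
  need <- c("row", "col", "radius", "fp_name", "expression")
  if (!all(need %in% colnames(cells)))
    stop(sprintf("cells needs columns %s", paste(need, collapse = ", ")))
  if (any(cells$radius <= 0)) stop("cell radii must be positive")
  out_of_bounds <- cells$row - cells$radius < 1 |
    cells$row + cells$radius > image_shape[1] |
    cells$col - cells$radius < 1 |
    cells$col + cells$radius > image_shape[2]
  if (any(out_of_bounds))
    stop(sprintf("cell(s) %s extend outside the image",
                 paste(which(out_of_bounds), collapse = ", ")))
  structure(list(image_shape = as.integer(image_shape), cells = cells,
                 background_level = background_level,
                 gaussian_sd = gaussian_sd, poisson = isTRUE(poisson),
                 seed = as.integer(seed)),
            class = "scene_spec")
}

#' Simulate a hyperspectral scene
#'
#' Renders each cell as a disc whose per-pixel expected intensity at every
#' channel is \code{expression x model_spectrum}, over a constant
#' background; then applies optional Poisson shot noise on the expected
#' counts and additive Gaussian read noise (clamped at zero). The exact
#' ground-truth label mask and per-cell FP labels are returned alongside
#' the stack, so every downstream statistic can be checked against truth.
#' Overlapping cells are permitted (later cells win mask pixels, signals
#' add) but reported with a warning.
#'
#' @param spec A \code{\link{scene_spec}}.
#' @param fps Named list of \code{\link{synthetic_fp}} covering every
#'   \code{fp_name} in the spec.
#' @param scheme An \code{\link{acquisition_scheme}}.
#' @return List with elements \code{stack} (\code{\link{hyper_stack}}),
#'   \code{mask} (\code{\link{label_mask}}, cell i labelled i), and
#'   \code{truth} (named character vector cell id -> FP name).
#' @export
simulate_scene <- function(spec, fps, scheme = default_scheme()) {
  stopifnot(inherits(spec, "scene_spec"))
  missing_fp <- setdiff(unique(spec$cells$fp_name), names(fps))
  if (length(missing_fp))
    stop(sprintf("undefined FP(s): %s", paste(missing_fp, collapse = ", ")))
  nr <- spec$image_shape[1]; nc <- spec$image_shape[2]
  nch <- scheme$total_channels
  spectra <- vapply(fps, model_spectrum, numeric(nch), scheme = scheme)
  n <- nrow(spec$cells)
  flat <- matrix(spec$background_level, nrow = nr * nc, ncol = nch)
  labels <- matrix(0L, nr, nc)
  overlap <- FALSE
  for (i in seq_len(n)) {
    ci <- spec$cells[i, ]
    rr <- max(1, floor(ci$row - ci$radius)):min(nr, ceiling(ci$row + ci$radius))
    cc <- max(1, floor(ci$col - ci$radius)):min(nc, ceiling(ci$col + ci$radius))
    g <- expand.grid(row = rr, col = cc)
    inside <- (g$row - ci$row)^2 + (g$col - ci$col)^2 <= ci$radius^2
    px <- g[inside, ]
    idx <- px$row + (px$col - 1L) * nr
    if (any(labels[idx] != 0L)) overlap <- TRUE
    labels[idx] <- i
    flat[idx, ] <- flat[idx, ] +
      rep(ci$expression * spectra[, ci$fp_name], each = length(idx))
  }
  if (overlap) warning("overlapping cells in scene")
  with_local_seed(spec$seed, {
    if (spec$poisson)
      flat <- matrix(stats::rpois(length(flat), lambda = flat), nrow = nr * nc)
    if (spec$gaussian_sd > 0)
      flat <- flat + stats::rnorm(length(flat), sd = spec$gaussian_sd)
  })
  flat[flat < 0] <- 0
  stack <- hyper_stack(array(flat, c(nr, nc, nch)), scheme)
  truth <- stats::setNames(as.character(spec$cells$fp_name), seq_len(n))
  list(stack = stack, mask = label_mask(labels), truth = truth)
}

# deterministic jittered-grid cell placement
place_cells <- function(n_cells, radius, seed, spacing = NULL) {
  if (is.null(spacing)) spacing <- 2 * radius + 3
  side <- ceiling(sqrt(n_cells))
  dim_px <- side * spacing + spacing
  centers <- expand.grid(row = (seq_len(side) - 0.5) * spacing + spacing / 2,
                         col = (seq_len(side) - 0.5) * spacing + spacing / 2)
  with_local_seed(seed, {
    pick <- sample.int(nrow(centers), n_cells)
    jit <- matrix(stats::runif(2 * n_cells, -1, 1), ncol = 2)
    data.frame(row = centers$row[pick] + jit[, 1],
               col = centers$col[pick] + jit[, 2],
               shape = rep(dim_px, n_cells))
  })
}

#' Simulate a full experimental design
#'
#' Generates ground-truthed scenes for the standard experimental designs:
#' \describe{
#'   \item{monoculture}{every cell expresses one FP (the first panel
#'     member unless \code{fp} names another).}
#'   \item{equal_mix}{FP labels drawn uniformly over the panel (a 1:1:...:1
#'     co-culture).}
#'   \item{fpmo}{FP-minus-one: labels drawn uniformly over the panel minus
#'     \code{missing_fp}, while decoding is still offered the full panel.}
#'   \item{clonal_growth}{founder cells grow into adjacent-disc clones day
#'     over day (clone size doubling, capped at 9) with per-day expression
#'     decay \code{dilution} emulating plasmid dilution across divisions;
#'     requires \code{days >= 2} and returns one scene per day.}
#' }
#' Expression levels are log-normal across cells
#' (\code{meanlog = log(500)}, \code{sdlog = 0.5}), emulating
#' transfection-level variation.
#'
#' @param design One of \code{"monoculture"}, \code{"equal_mix"},
#'   \code{"fpmo"}, \code{"clonal_growth"}.
#' @param fps Named list of \code{\link{synthetic_fp}} (the panel).
#' @param n_cells Cells per scene (founders, for clonal growth).
#' @param seed RNG seed.
#' @param fp Monoculture FP name (default: first panel member).
#' @param missing_fp FpMO omitted FP (default: last panel member).
#' @param days Number of days for clonal growth (>= 2).
#' @param radius Cell radius in pixels (default 3).
#' @param expression_meanlog,expression_sdlog Log-normal expression
#'   parameters.
#' @param dilution Per-day expression multiplier for clonal growth
#'   (default 0.6).
#' @param background_level,gaussian_sd,poisson Noise model passed to
#'   \code{\link{scene_spec}}.
#' @param scheme An \code{\link{acquisition_scheme}}.
#' @return For single-scene designs, the \code{\link{simulate_scene}} list;
#'   for \code{clonal_growth}, a list of per-day scene lists.
#' @export
simulate_experiment <- function(design = c("monoculture", "equal_mix",
                                           "fpmo", "clonal_growth"),
                                fps, n_cells, seed,
                                fp = NULL, missing_fp = NULL, days = 3,
                                radius = 3,
                                expression_meanlog = log(500),
                                expression_sdlog = 0.5,
                                dilution = 0.6,
                                background_level = 2, gaussian_sd = 3,
                                poisson = FALSE,
                                scheme = default_scheme()) {
  design <- match.arg(design)
  panel <- names(fps)
  draw_expr <- function(k, s) with_local_seed(s,
    stats::rlnorm(k, expression_meanlog, expression_sdlog))
  if (design != "clonal_growth") {
    pos <- place_cells(n_cells, radius, seed)
    labels <- switch(design,
      monoculture = rep(if (is.null(fp)) panel[1] else fp, n_cells),
      equal_mix = with_local_seed(seed + 1,
        sample(panel, n_cells, replace = TRUE)),
      fpmo = {
        if (is.null(missing_fp)) missing_fp <- panel[length(panel)]
        if (!missing_fp %in% panel) stop("missing_fp not in panel")
        with_local_seed(seed + 1,
          sample(setdiff(panel, missing_fp), n_cells, replace = TRUE))
      })
    if (design == "monoculture" && !all(labels %in% panel))
      stop("monoculture fp not in panel")
    cells <- data.frame(row = pos$row, col = pos$col, radius = radius,
                        fp_name = labels,
                        expression = draw_expr(n_cells, seed + 2))
    sp <- scene_spec(c(pos$shape[1], pos$shape[1]), cells,
                     background_level = background_level,
                     gaussian_sd = gaussian_sd, poisson = poisson,
                     seed = seed + 3)
    return(simulate_scene(sp, fps, scheme))
  }
  # clonal growth: founders on a coarse grid, clones expand as rings of
  # touching discs within a 3x3 neighbourhood of the founder
  if (days < 2) stop("clonal_growth needs days >= 2")
  spacing <- 3 * (2 * radius + 2) + 4
  pos <- place_cells(n_cells, radius, seed, spacing = spacing)
  founder_fp <- with_local_seed(seed + 1,
    sample(panel, n_cells, replace = TRUE))
  founder_expr <- draw_expr(n_cells, seed + 2)
  offsets <- expand.grid(dr = c(0, -1, 1), dc = c(0, -1, 1))
  offsets <- offsets[order(abs(offsets$dr) + abs(offsets$dc)), ]
  lapply(seq_len(days), function(day) {
    size <- min(2^(day - 1), 9)
    rows <- cols <- fpn <- ex <- c()
    for (i in seq_len(n_cells)) {
      o <- offsets[seq_len(size), ]
      rows <- c(rows, pos$row[i] + o$dr * (2 * radius + 1))
      cols <- c(cols, pos$col[i] + o$dc * (2 * radius + 1))
      fpn <- c(fpn, rep(founder_fp[i], size))
      ex <- c(ex, rep(founder_expr[i] * dilution^(day - 1), size))
    }
    cells <- data.frame(row = rows, col = cols, radius = radius,
                        fp_name = fpn, expression = ex)
    sp <- scene_spec(c(pos$shape[1] + 2 * spacing, pos$shape[1] + 2 * spacing),
                     data.frame(row = cells$row + spacing,
                                col = cells$col + spacing,
                                radius = cells$radius,
                                fp_name = cells$fp_name,
                                expression = cells$expression),
                     background_level = background_level,
                     gaussian_sd = gaussian_sd, poisson = poisson,
                     seed = seed + 10 + day)
    simulate_scene(sp, fps, scheme)
  })
}
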