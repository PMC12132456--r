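#' FP colour map
#'
#' Maps FP names to RGB triples (0-255) for paint-by-number rendering.
#' When the user supplies no colours, a fixed 16-colour cycle is assigned
#' in the order the FPs are given.
#'
#' @param fps Character vector of FP names, or a named list of RGB triples.
#' @param unclassified_color RGB triple for unclassified cells (default
#'   mid-grey).
#' @return An object of class \code{fp_colormap}: a named list of integer
#'   RGB triples plus the unclassified colour.
#' @export
fp_colormap <- function(fps, unclassified_color = c(128L, 128L, 128L)) {
  cycle <- list(
    c(230,  25,  75), c( 60, 180,  75), c(255, 225,  25), c(  0, 130, 200),
    c(245, 130,  48), c(145,  30, 180), c( 70, 240, 240), c(240,  50, 230),
    c(210, 245,  60), c(250, 190, 212), c(  0, 128, 128), c(220, 190, 255),
    c(170, 110,  40), c(255, 250, 200), c(128,   0,   0), c(170, 255, 195))
  if (is.list(fps)) {
    colors <- lapply(fps, function(v) {
      v <- as.integer(v)
      if (length(v) != 3 || any(v < 0) || any(v > 255))
        stop("colors must be RGB triples in 0-255")
      v
    })
  } else {
    colors <- stats::setNames(
      cycle[(seq_along(fps) - 1L) %% length(cycle) + 1L], fps)
  }
  structure(list(colors = colors,
                 unclassified_color = as.integer(unclassified_color)),
            class = "fp_colormap")
}

color_of <- function(colormap, fp) {
  if (fp == "unclassified") return(colormap$unclassified_color)
  col <- colormap$colors[[fp]]
  if (is.null(col)) stop(sprintf("no color for FP '%s'", fp))
  col
}

#' Complementary colour
#'
#' The complement of (r, g, b) is (255-r, 255-g, 255-b); used for highlight
#' outlines so they contrast with the cell fill.
#'
#' @param rgb Integer RGB triple (0-255).
#' @return Integer RGB triple.
#' @export
complementary_color <- function(rgb) 255L - as.integer(rgb)

#' Rendering options
#'
#' @param show_outlines Outline every visible cell?
#' @param color_enabled \code{FALSE} renders everything grayscale.
#' @param visible_fps Optional subset of FPs to colour; others render
#'   grayscale.
#' @param highlight_cells Optional cell ids to outline in the complementary
#'   colour of their fill.
#' @param intensity_gamma Positive gamma applied to both the grayscale
#'   background and the per-cell brightness factor.
#' @return An object of class \code{render_options}.
#' @export
render_options <- function(show_outlines = FALSE, color_enabled = TRUE,
                           visible_fps = NULL, highlight_cells = NULL,
                           intensity_gamma = 1) {
  if (intensity_gamma <= 0) stop("intensity_gamma must be positive")
  structure(list(show_outlines = isTRUE(show_outlines),
                 color_enabled = isTRUE(color_enabled),
                 visible_fps = visible_fps,
                 highlight_cells = highlight_cells,
                 intensity_gamma = intensity_gamma),
            class = "render_options")
}

# boundary pixels of each labelled region (4-neighbourhood)
outline_pixels <- function(labels) {
  nr <- nrow(labels); nc <- ncol(labels)
  pad <- matrix(-1L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- labels
  core <- pad[2:(nr + 1), 2:(nc + 1)]
  differs <- (core != pad[1:nr, 2:(nc + 1)]) |
             (core != pad[3:(nr + 2), 2:(nc + 1)]) |
             (core != pad[2:(nr + 1), 1:nc]) |
             (core != pad[2:(nr + 1), 3:(nc + 2)])
  differs & labels > 0
}

#' Paint-by-number rendering of a decoded scene
#'
#' Produces an RGB image in which non-cell regions show the grayscale
#' maximum intensity projection, and each cell's mask pixels are filled
#' with the colour of its predicted FP, brightness-scaled by the cell's
#' radiance: log10 radiance is min-max scaled across the image to
#' [0.3, 1] (the 0.3 floor keeps dim cells visible) and multiplied into
#' the fill colour. FPs outside \code{visible_fps} — and everything, when
#' \code{color_enabled} is off — render grayscale. Highlighted cells get a
#' complementary-colour outline; \code{show_outlines} outlines every
#' visible cell.
#'
#' @param mip Grayscale projection image (rows x cols).
#' @param mask A \code{\link{label_mask}} of the same shape.
#' @param result The \code{\link{classify_cells}} result for these cells.
#' @param cells The \code{\link{cell_spectra}} matrix (for radiance).
#' @param colors An \code{\link{fp_colormap}}; default cycle over the
#'   result's candidates when \code{NULL}.
#' @param options A \code{\link{render_options}}.
#' @return A rows x cols x 3 array in [0, 1], suitable for
#'   \code{png::writePNG}.
#' @export
render_classification <- function(mip, mask, result, cells, colors = NULL,
                                  options = render_options()) {
  stopifnot(inherits(mask, "label_mask"),
            inherits(result, "classification_result"),
            inherits(cells, "cell_spectra"))
  mip <- as.matrix(mip)
  if (!all(dim(mip) == dim(mask$labels)))
    stop("mip and mask shapes do not match")
  mask_ids <- setdiff(unique(as.vector(mask$labels)), 0L)
  unknown <- setdiff(mask_ids, result$cell_ids)
  if (length(unknown))
    stop(sprintf("mask cell id(s) missing from classification: %s",
                 paste(sort(unknown), collapse = ", ")))
  if (is.null(colors)) colors <- fp_colormap(result$candidates)
  gamma <- options$intensity_gamma

  gray <- if (max(mip) > 0) (mip / max(mip))^gamma else mip
  out <- array(rep(gray, 3), c(dim(mip), 3))
  if (!options$color_enabled) return(out)

  pred <- stats::setNames(result$predicted_fp, result$cell_ids)
  r <- stats::setNames(radiance(cells$matrix), cells$cell_ids)
  lr <- ifelse(r > 0, log10(pmax(r, 1e-12)), NA)
  rng <- range(lr, na.rm = TRUE)
  bright <- if (diff(rng) > 0) 0.3 + 0.7 * ((lr - rng[1]) / diff(rng))^gamma
            else stats::setNames(rep(1, length(lr)), names(lr))
  bright[is.na(bright)] <- 0.3

  visible <- function(fp) {
    fp != "unclassified" &&
      (is.null(options$visible_fps) || fp %in% options$visible_fps)
  }
  outlines <- if (options$show_outlines || length(options$highlight_cells))
    outline_pixels(mask$labels) else NULL
  for (id in mask_ids) {
    fp <- pred[[as.character(id)]]
    if (!visible(fp)) next
    sel <- mask$labels == id
    fill <- color_of(colors, fp) / 255 * bright[[as.character(id)]]
    for (k in 1:3) {
      plane <- out[, , k]
      plane[sel] <- fill[k]
      out[, , k] <- plane
    }
    edge <- NULL
    if (!is.null(outlines) &&
        (options$show_outlines || id %in% options$highlight_cells))
      edge <- sel & outlines
    if (id %in% options$highlight_cells || (options$show_outlines && !is.null(edge))) {
      oc <- complementary_color(color_of(colors, fp)) / 255
      for (k in 1:3) {
        plane <- out[, , k]
        plane[edge] <- oc[k]
        out[, , k] <- plane
      }
    }
  }
  out
}

#' Write a rendered image as 8-bit PNG
#'
#' @param img rows x cols x 3 array in [0, 1].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_render <- function(img, path) {
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

#' Per-FP cell counts of a classification
#'
#' The legend of a painted image: how many cells were called as each FP
#' (including \code{"unclassified"}); counts always partition the total.
#'
#' @param result A \code{\link{classify_cells}} result.
#' @return Named integer vector over candidates (+ unclassified when
#'   present).
#' @export
legend_counts <- function(result) {
  stopifnot(inherits(result, "classification_result"))
  if (!length(result$cell_ids)) stop("empty classification result")
  lev <- c(result$candidates,
           if ("unclassified" %in% result$predicted_fp) "unclassified")
  tab <- table(factor(result$predicted_fp, levels = lev))
  stats::setNames(as.integer(tab), names(tab))
}

#' Retrieve one cell's spectrum and its predicted reference
#'
#' The non-interactive equivalent of clicking a cell in a viewer: returns
#' the cell's measured spectrum, the reference spectrum of its predicted
#' FP, and their cosine similarity, ready for side-by-side plotting.
#'
#' @param cells A \code{\link{cell_spectra}} matrix.
#' @param result The matching \code{\link{classify_cells}} result.
#' @param library The \code{\link{reference_library}} used for decoding.
#' @param cell_id The cell to retrieve.
#' @return List with \code{cell_id}, \code{spectrum}, \code{predicted_fp},
#'   \code{reference} (NULL for unclassified cells), and \code{mcs}.
#' @export
cell_spectrum <- function(cells, result, library, cell_id) {
  stopifnot(inherits(cells, "cell_spectra"),
            inherits(result, "classification_result"),
            inherits(library, "reference_library"))
  i <- match(cell_id, cells$cell_ids)
  if (is.na(i)) stop(sprintf("unknown cell id %s", cell_id))
  j <- match(cell_id, result$cell_ids)
  if (is.na(j)) stop(sprintf("cell id %s missing from classification", cell_id))
  fp <- result$predicted_fp[j]
  ref <- if (fp == "unclassified") NULL
         else library$references[[fp]]$spectrum
  list(cell_id = cell_id,
       spectrum = cells$matrix[i, ],
       predicted_fp = fp,
       reference = ref,
       mcs = result$mcs_value[j])
}
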