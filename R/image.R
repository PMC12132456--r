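#' Hyperspectral image stack
#'
#' A rows x cols x channels array of non-negative intensities together with
#' the acquisition scheme that produced it. The channel dimension is the
#' block-concatenated spectral axis (100 channels under the default scheme).
#'
#' @param pixels Numeric array with \code{dim = c(rows, cols, channels)};
#'   all entries must be >= 0.
#' @param scheme The \code{\link{acquisition_scheme}} of the acquisition.
#' @return An object of class \code{hyper_stack}.
#' @export
hyper_stack <- function(pixels, scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  if (length(dim(pixels)) != 3)
    stop("pixels must be a rows x cols x channels array")
  if (dim(pixels)[3] != scheme$total_channels)
    stop(sprintf("stack has %d channels but the scheme defines %d",
                 dim(pixels)[3], scheme$total_channels))
  if (any(pixels < 0)) stop("stack intensities must be non-negative")
  structure(list(pixels = pixels, scheme = scheme), class = "hyper_stack")
}

#' @export
print.hyper_stack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("Hyperspectral stack: %d x %d pixels, %d channels\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Load block TIFFs (or one concatenated file) into a stack
#'
#' Reads one multi-page grayscale TIFF per acquisition block and concatenates
#' the channel pages in block order; a single path holding all channels of
#' the scheme is accepted as a pre-concatenated stack. Pixel values are read
#' as stored (integer counts are not rescaled).
#'
#' @param block_paths Character vector of TIFF paths, one per block, or a
#'   single path to a pre-concatenated stack.
#' @param scheme An \code{acquisition_scheme}.
#' @return A \code{\link{hyper_stack}}.
#' @export
load_stacks <- function(block_paths, scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  read_pages <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    lapply(pages, function(p) {
      if (length(dim(p)) == 3) p <- p[, , 1]  # ignore extra samples
      p
    })
  }
  n_blocks <- length(scheme$blocks)
  if (length(block_paths) == 1 && n_blocks > 1) {
    pages <- read_pages(block_paths)
    if (length(pages) != scheme$total_channels)
      stop(sprintf("%s: expected %d channels, found %d",
                   block_paths, scheme$total_channels, length(pages)))
  } else {
    if (length(block_paths) != n_blocks)
      stop(sprintf("expected %d block files (or one concatenated file), got %d",
                   n_blocks, length(block_paths)))
    pages <- list()
    for (i in seq_len(n_blocks)) {
      p <- read_pages(block_paths[i])
      expected <- scheme$blocks[[i]]$n_channels
      if (length(p) != expected)
        stop(sprintf("%s: expected %d channels, found %d",
                     block_paths[i], expected, length(p)))
      pages <- c(pages, p)
    }
  }
  shapes <- unique(lapply(pages, dim))
  if (length(shapes) != 1)
    stop("all channels must share the same row/col dimensions")
  arr <- array(0, c(shapes[[1]], length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]]
  hyper_stack(arr, scheme)
}

#' Write a stack as 16-bit multi-page TIFF(s)
#'
#' Values are rounded to integer counts and must lie in [0, 65535]. With
#' \code{split_blocks = TRUE} one file per acquisition block is written
#' (suffix \code{_block<i>.tif}), mirroring how the microscope emits four
#' files per field of view; otherwise a single concatenated stack.
#'
#' @param stack A \code{\link{hyper_stack}}.
#' @param path Output path (used as a prefix when splitting).
#' @param split_blocks Write one file per block?
#' @return Character vector of the paths written, invisibly.
#' @export
write_stack <- function(stack, path, split_blocks = FALSE) {
  stopifnot(inherits(stack, "hyper_stack"))
  px <- round(stack$pixels)
  px[px < 0] <- 0
  if (max(px) > 65535)
    stop("intensities exceed the 16-bit range; rescale before writing")
  to_pages <- function(a) lapply(seq_len(dim(a)[3]), function(k) a[, , k] / 65535)
  if (split_blocks) {
    prefix <- sub("\\.tiff?$", "", path)
    offsets <- c(0, cumsum(vapply(stack$scheme$blocks, `[[`, 1L, "n_channels")))
    paths <- character(length(stack$scheme$blocks))
    for (i in seq_along(stack$scheme$blocks)) {
      idx <- (offsets[i] + 1):offsets[i + 1]
      paths[i] <- sprintf("%s_block%d.tif", prefix, i)
      tiff::writeTIFF(to_pages(px[, , idx, drop = FALSE]), paths[i],
                      bits.per.sample = 16L)
    }
  } else {
    tiff::writeTIFF(to_pages(px), path, bits.per.sample = 16L)
    paths <- path
  }
  invisible(paths)
}

#' Label mask
#'
#' An integer image in which 0 is background and each positive integer
#' labels the pixels of one cell. Masks may come from any segmentation tool
#' (e.g. a Cellpose pipeline) or from \code{\link{segment_mip}}.
#'
#' @param labels Integer matrix (rows x cols), values >= 0.
#' @return An object of class \code{label_mask} with an \code{n_cells} field.
#' @export
label_mask <- function(labels) {
  labels <- as.matrix(labels)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("mask labels must be non-negative integers")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels,
                 n_cells = length(setdiff(unique(as.vector(labels)), 0L))),
            class = "label_mask")
}

#' Read / write a label mask (16-bit TIFF or PNG)
#'
#' @param path File path; format chosen by extension (.png or .tif/.tiff).
#' @param mask A \code{\link{label_mask}} (for writing).
#' @return \code{read_mask} returns a \code{label_mask}.
#' @export
read_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- img[, , 1]
    labels <- round(img * 65535)
  } else {
    labels <- tiff::readTIFF(path, as.is = TRUE)
    if (length(dim(labels)) == 3) labels <- labels[, , 1]
  }
  label_mask(labels)
}

#' @rdname read_mask
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "label_mask"))
  if (max(mask$labels) > 65535) stop("labels exceed the 16-bit range")
  img <- mask$labels / 65535
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(img, path)
  } else {
    tiff::writeTIFF(img, path, bits.per.sample = 16L)
  }
  invisible(path)
}

#' Maximum intensity projection
#'
#' Collapses the channel axis by taking the per-pixel maximum across all
#' channels, producing the single grayscale image used for segmentation and
#' as the background of rendered images.
#'
#' @param stack A \code{\link{hyper_stack}} or rows x cols x channels array.
#' @return A rows x cols matrix.
#' @export
max_intensity_projection <- function(stack) {
  px <- if (inherits(stack, "hyper_stack")) stack$pixels else stack
  stopifnot(length(dim(px)) == 3)
  apply(px, c(1, 2), max)
}

#' Built-in fallback segmentation of a projection image
#'
#' Gaussian smoothing, Otsu threshold, connected-component labelling,
#' watershed splitting on the distance transform, then removal of components
#' below \code{min_area}. This is a simple deterministic segmenter so the
#' pipeline runs without an external model; for real data an externally
#' generated mask (e.g. Cellpose) supplied via \code{\link{read_mask}} is
#' expected to be superior and is accepted everywhere a mask is used.
#'
#' @param mip 2-D non-negative image matrix.
#' @param min_area Minimum object area in pixels (default 20).
#' @param smoothing_sigma Gaussian smoothing sigma in pixels (default 2).
#' @return A \code{\link{label_mask}}; an all-background result has
#'   \code{n_cells = 0} and is not an error.
#' @export
segment_mip <- function(mip, min_area = 20, smoothing_sigma = 2) {
  mip <- as.matrix(mip)
  if (any(mip < 0)) stop("projection image must be non-negative")
  if (max(mip) == 0) return(label_mask(matrix(0L, nrow(mip), ncol(mip))))
  img <- EBImage::Image(mip / max(mip))
  sm <- EBImage::gblur(img, sigma = smoothing_sigma)
  thr <- EBImage::otsu(sm, range = c(0, 1))
  bw <- sm > thr
  if (sum(bw) == 0) return(label_mask(matrix(0L, nrow(mip), ncol(mip))))
  dist <- EBImage::distmap(bw)
  lab <- EBImage::watershed(dist, tolerance = 1)
  m <- EBImage::imageData(lab)
  sizes <- tabulate(m[m > 0])
  keep <- which(sizes >= min_area)
  relabel <- integer(length(sizes))
  relabel[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(m), ncol(m))
  pos <- m > 0
  out[pos] <- relabel[m[pos]]
  label_mask(out)
}

#' Per-cell mean spectra from a stack and a mask
#'
#' For every cell label, the mean pixel intensity is computed at each channel
#' over that cell's mask pixels, giving the cell x channel intensity matrix
#' that all decoding operates on. Rows are ordered by ascending cell id.
#'
#' @param stack A \code{\link{hyper_stack}}.
#' @param mask A \code{\link{label_mask}} of the same row/col shape.
#' @param truth_labels Optional named character vector (names = cell ids) or
#'   unnamed vector in ascending-id order, recording ground-truth FP labels.
#' @return A \code{\link{cell_spectra}} object.
#' @export
extract_cell_spectra <- function(stack, mask, truth_labels = NULL) {
  stopifnot(inherits(stack, "hyper_stack"), inherits(mask, "label_mask"))
  d <- dim(stack$pixels)
  if (!all(d[1:2] == dim(mask$labels)))
    stop("stack and mask shapes do not match")
  if (mask$n_cells < 1) stop("mask contains no cells")
  ids <- sort(setdiff(unique(as.vector(mask$labels)), 0L))
  lab <- as.vector(mask$labels)
  inside <- lab > 0
  flat <- matrix(stack$pixels, nrow = d[1] * d[2], ncol = d[3])
  sums <- rowsum(flat[inside, , drop = FALSE], group = lab[inside])
  counts <- as.vector(table(lab[inside]))
  m <- sums / counts
  rownames(m) <- NULL
  if (!is.null(truth_labels)) {
    if (!is.null(names(truth_labels))) {
      truth_labels <- unname(truth_labels[as.character(ids)])
    } else if (length(truth_labels) != length(ids)) {
      stop("truth_labels length does not match number of cells")
    }
  }
  cell_spectra(ids, m, truth_labels = truth_labels, source = "extract_cell_spectra")
}
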