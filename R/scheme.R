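#' Acquisition block
#'
#' One sequential spectral scan: a fixed set of excitation laser lines and a
#' contiguous emission detection range split into equal-width channels.
#'
#' @param block_index Integer position of the block (1-4 in the default
#'   scheme); concatenation follows this order.
#' @param laser_lines_nm Numeric vector of excitation wavelengths (nm).
#' @param emission_start_nm,emission_end_nm Emission detection range (nm);
#'   start must be below end.
#' @param n_channels Number of detector channels in the block.
#' @param channel_width_nm Nominal channel bandwidth (nm); default 8.9.
#'
#' @return An object of class \code{acquisition_block}.
#' @export
acquisition_block <- function(block_index, laser_lines_nm,
                              emission_start_nm, emission_end_nm,
                              n_channels, channel_width_nm = 8.9) {
  stopifnot(length(block_index) == 1, block_index >= 1,
            length(n_channels) == 1)
  if (!(emission_start_nm < emission_end_nm))
    stop("emission_start_nm must be below emission_end_nm")
  if (n_channels < 1) stop("n_channels must be >= 1")
  if (length(laser_lines_nm) < 1 || any(laser_lines_nm <= 0))
    stop("laser_lines_nm must be positive wavelengths")
  structure(list(
    block_index = as.integer(block_index),
    laser_lines_nm = as.numeric(laser_lines_nm),
    emission_start_nm = as.numeric(emission_start_nm),
    emission_end_nm = as.numeric(emission_end_nm),
    n_channels = as.integer(n_channels),
    channel_width_nm = as.numeric(channel_width_nm)
  ), class = "acquisition_block")
}

#' Acquisition scheme
#'
#' An ordered list of acquisition blocks whose channels concatenate, block by
#' block, into a single per-cell spectrum.
#'
#' @param blocks List of \code{\link{acquisition_block}} objects, in
#'   concatenation order.
#'
#' @return An object of class \code{acquisition_scheme} with a
#'   \code{total_channels} field equal to the summed block channel counts.
#' @export
acquisition_scheme <- function(blocks) {
  if (!length(blocks) || !all(vapply(blocks, inherits, TRUE, "acquisition_block")))
    stop("blocks must be a non-empty list of acquisition_block objects")
  structure(list(
    blocks = blocks,
    total_channels = sum(vapply(blocks, `[[`, 1L, "n_channels"))
  ), class = "acquisition_scheme")
}

#' Default 4-block, 100-channel acquisition scheme
#'
#' The standard acquisition geometry: block 1 (405 nm laser, emission
#' 420-695 nm, 31 channels), block 2 (458/561 nm, 455-695 nm, 27 channels),
#' block 3 (488 nm, 500-695 nm, 22 channels), block 4 (514/594 nm,
#' 517-695 nm, 20 channels), totalling 100 channels at ~8.9 nm bandwidth.
#'
#' @return An \code{acquisition_scheme} with \code{total_channels = 100}.
#' @export
default_scheme <- function() {
  acquisition_scheme(list(
    acquisition_block(1L, 405,          420, 695, 31L),
    acquisition_block(2L, c(458, 561),  455, 695, 27L),
    acquisition_block(3L, 488,          500, 695, 22L),
    acquisition_block(4L, c(514, 594),  517, 695, 20L)
  ))
}

#' Channel center wavelengths of a scheme
#'
#' Channel k (1-based) of a block is centred at
#' \code{emission_start_nm + (k - 0.5) * channel_width_nm}. The grid is a
#' convention: acquisition software reports ranges and a nominal bandwidth,
#' not centres, and a deterministic grid is required by the simulator.
#'
#' @param scheme An \code{acquisition_scheme}.
#' @return Numeric vector of length \code{scheme$total_channels} (nm),
#'   in block concatenation order.
#' @export
channel_centers <- function(scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  unlist(lapply(scheme$blocks, function(b) {
    b$emission_start_nm + (seq_len(b$n_channels) - 0.5) * b$channel_width_nm
  }), use.names = FALSE)
}

#' Concatenate per-block spectra into one spectrum
#'
#' Joins one intensity vector per acquisition block, in block order, into a
#' single spectrum of length \code{scheme$total_channels}.
#'
#' @param block_spectra List with one numeric vector per block; lengths must
#'   match the per-block channel counts.
#' @param scheme An \code{acquisition_scheme}.
#' @return Numeric vector of length \code{scheme$total_channels}.
#' @export
concatenate_blocks <- function(block_spectra, scheme) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  n_blocks <- length(scheme$blocks)
  if (length(block_spectra) != n_blocks)
    stop(sprintf("expected %d block spectra, got %d",
                 n_blocks, length(block_spectra)))
  for (i in seq_len(n_blocks)) {
    expected <- scheme$blocks[[i]]$n_channels
    got <- length(block_spectra[[i]])
    if (got != expected)
      stop(sprintf("block %d: expected %d channels, got %d", i, expected, got))
  }
  unlist(lapply(block_spectra, as.numeric), use.names = FALSE)
}

#' Read or write an acquisition scheme as JSON
#'
#' The JSON holds one object per block with keys \code{laser_lines_nm},
#' \code{emission_start_nm}, \code{emission_end_nm}, \code{n_channels},
#' \code{channel_width_nm}.
#'
#' @param path File path.
#' @param scheme An \code{acquisition_scheme} (for writing).
#' @return \code{read_scheme} returns an \code{acquisition_scheme};
#'   \code{write_scheme} returns \code{path} invisibly.
#' @export
read_scheme <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  blocks <- lapply(seq_along(raw), function(i) {
    b <- raw[[i]]
    acquisition_block(i, unlist(b$laser_lines_nm),
                      b$emission_start_nm, b$emission_end_nm,
                      b$n_channels,
                      if (is.null(b$channel_width_nm)) 8.9 else b$channel_width_nm)
  })
  acquisition_scheme(blocks)
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "acquisition_scheme"))
  out <- lapply(scheme$blocks, function(b) {
    list(laser_lines_nm = b$laser_lines_nm,
         emission_start_nm = b$emission_start_nm,
         emission_end_nm = b$emission_end_nm,
         n_channels = b$n_channels,
         channel_width_nm = b$channel_width_nm)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.acquisition_scheme <- function(x, ...) {
  cat(sprintf("Acquisition scheme: %d blocks, %d channels total\n",
              length(x$blocks), x$total_channels))
  for (b in x$blocks) {
    cat(sprintf("  block %d: lasers %s nm, emission %g-%g nm, %d channels\n",
                b$block_index, paste(b$laser_lines_nm, collapse = "/"),
                b$emission_start_nm, b$emission_end_nm, b$n_channels))
  }
  invisible(x)
}
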