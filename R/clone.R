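#' Spatial clone misclassification model
#'
#' Cells of a clone share one true FP, and per-cell misclassification
#' events are modelled as independent with probability \code{p} (the
#' monoculture error rate as a fraction). A clone of N cells is entirely
#' mislabelled — the failure mode that would corrupt clone tracking — with
#' probability \code{p^N}, which falls exponentially in clone size: a
#' per-cell error of 0.32\% gives ~1e-5 for two adjacent cells.
#' Clones live on a 3x3 neighbourhood grid with the founding cell fixed at
#' the centre and the remaining N-1 cells on the 8 surrounding squares.
#'
#' @param per_cell_error_p Per-cell misclassification probability in [0, 1]
#'   (a rate of 0.32\% is \code{p = 0.0032}).
#' @return An object of class \code{clone_error_model}
#'   (\code{grid_size = 3}, \code{max_clone = 9}).
#' @export
clone_error_model <- function(per_cell_error_p) {
  if (per_cell_error_p < 0 || per_cell_error_p > 1)
    stop("per_cell_error_p must be in [0, 1]")
  structure(list(per_cell_error_p = per_cell_error_p,
                 grid_size = 3L, max_clone = 9L),
            class = "clone_error_model")
}

check_clone_size <- function(model, n) {
  if (length(n) != 1 || n != round(n) || n < 1 || n > model$max_clone)
    stop(sprintf("clone size must be an integer in 1..%d", model$max_clone))
  as.integer(n)
}

#' Probability an entire clone is misclassified
#'
#' @param model A \code{\link{clone_error_model}}.
#' @param n Clone size (1-9).
#' @return \code{p^n}.
#' @export
clone_misclassification_probability <- function(model, n) {
  stopifnot(inherits(model, "clone_error_model"))
  n <- check_clone_size(model, n)
  model$per_cell_error_p^n
}

#' Number of distinct clone placements on the 3x3 grid
#'
#' With the centre square always occupied by the founding cell, the other
#' n-1 cells occupy some subset of the 8 surrounding squares, giving
#' \code{choose(8, n - 1)} distinct placements. Summed over clone sizes
#' 1..9 this covers all 2^8 = 256 subsets of the outer ring.
#'
#' @param n Clone size (1-9).
#' @return Integer placement count.
#' @export
placement_count <- function(n) {
  n <- check_clone_size(list(max_clone = 9L), n)
  choose(8, n - 1)
}

#' Monte-Carlo clone misclassification
#'
#' Simulates clone placements (centre fixed, the n-1 remaining cells
#' uniform over the outer-ring subsets) and independent per-cell errors,
#' returning the empirical fraction of replicates in which every cell of
#' the clone was misclassified. Placement does not alter the probability —
#' errors are position-independent — but is simulated so spatial extensions
#' can hook in; the estimate converges to
#' \code{\link{clone_misclassification_probability}}.
#'
#' @param model A \code{\link{clone_error_model}}.
#' @param n Clone size (1-9).
#' @param reps Number of replicates (>= 1).
#' @param seed RNG seed; the same seed gives a bit-identical result.
#' @return Empirical probability in [0, 1].
#' @export
simulate_clone_errors <- function(model, n, reps, seed) {
  stopifnot(inherits(model, "clone_error_model"))
  n <- check_clone_size(model, n)
  if (reps < 1) stop("reps must be >= 1")
  if (missing(seed)) stop("a seed is required for reproducibility")
  with_local_seed(seed, {
    # per-replicate placement: one of the choose(8, n-1) outer-ring subsets,
    # uniformly; drawn as an index since position does not affect the errors
    placements <- sample.int(placement_count(n), reps, replace = TRUE)
    errors <- matrix(stats::runif(reps * n) < model$per_cell_error_p,
                     nrow = reps)
    mean(rowSums(errors) == n)
  })
}

# evaluate expr under a temporary RNG state, restoring the caller's state
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Clone-error table over clone sizes
#'
#' @param model A \code{\link{clone_error_model}}.
#' @param sizes Clone sizes to tabulate (default 1:9).
#' @param reps Monte-Carlo replicates per size; \code{0} skips simulation.
#' @param seed RNG seed used when \code{reps > 0}.
#' @return data.frame with columns \code{n}, \code{placements},
#'   \code{analytic}, and \code{empirical} when simulated.
#' @export
clone_error_table <- function(model, sizes = 1:9, reps = 0, seed = 1) {
  stopifnot(inherits(model, "clone_error_model"))
  df <- data.frame(n = sizes,
                   placements = vapply(sizes, placement_count, 0),
                   analytic = vapply(sizes, function(n)
                     clone_misclassification_probability(model, n), 0))
  if (reps > 0)
    df$empirical <- vapply(seq_along(sizes), function(i)
      simulate_clone_errors(model, sizes[i], reps, seed + i), 0)
  df
}
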