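#' Palette query
#'
#' Parameters of an N-tuple palette search: the tuple size, the pairwise
#' similarity cutoff below which two FPs are considered spectrally
#' resolvable, and optional include/exclude constraints.
#'
#' @param n Tuple size (2-15).
#' @param threshold Resolvability cutoff (default 0.9).
#' @param strict If \code{TRUE} (default) a pair is feasible when its
#'   similarity is strictly \code{< threshold}; if \code{FALSE},
#'   \code{<= threshold}.
#' @param include FP names that must appear in every returned palette.
#' @param exclude FP names barred from all palettes.
#' @param max_results Cap on the number of solutions returned (default
#'   10000); when the cap truncates the sorted list the result carries
#'   \code{attr(, "truncated") = TRUE}.
#' @return An object of class \code{palette_query}.
#' @export
palette_query <- function(n, threshold = 0.9, strict = TRUE,
                          include = character(), exclude = character(),
                          max_results = 10000L) {
  if (n < 2 || n > 15) stop("tuple size n must be between 2 and 15")
  if (length(intersect(include, exclude)))
    stop("include and exclude sets overlap")
  if (n < length(include)) stop("n is smaller than the include set")
  structure(list(n = as.integer(n), threshold = threshold,
                 strict = isTRUE(strict),
                 include = include, exclude = exclude,
                 max_results = as.integer(max_results)),
            class = "palette_query")
}

#' Palette solution
#'
#' A candidate FP palette: its members, their pairwise-similarity submatrix,
#' and the objective — the sum of similarities over all unordered member
#' pairs (smaller = more mutually resolvable).
#'
#' @param fp_names_set Character vector of member FP names.
#' @param submatrix Their pairwise similarity submatrix.
#' @param threshold,strict Feasibility rule used to set \code{feasible}.
#' @return An object of class \code{palette_solution} with fields
#'   \code{fp_names}, \code{submatrix}, \code{objective}, \code{feasible}.
#' @export
palette_solution <- function(fp_names_set, submatrix, threshold = 0.9,
                             strict = TRUE) {
  submatrix <- as.matrix(submatrix)
  off <- submatrix[upper.tri(submatrix)]
  ok <- if (strict) all(off < threshold) else all(off <= threshold)
  structure(list(fp_names = fp_names_set,
                 submatrix = submatrix,
                 objective = sum(off),
                 feasible = ok),
            class = "palette_solution")
}

#' @export
print.palette_solution <- function(x, ...) {
  cat(sprintf("%d-tuple {%s}: objective %.4f%s\n", length(x$fp_names),
              paste(x$fp_names, collapse = ", "), x$objective,
              if (x$feasible) "" else " (infeasible)"))
  invisible(x)
}

check_similarity_matrix <- function(matrix) {
  if (!is.matrix(matrix) || nrow(matrix) != ncol(matrix))
    stop("similarity matrix must be square")
  if (is.null(rownames(matrix)))
    stop("similarity matrix must carry FP names as dimnames")
  if (max(abs(matrix - t(matrix))) > 1e-12)
    stop("similarity matrix must be symmetric")
  if (any(abs(diag(matrix) - 1) > 1e-12))
    stop("similarity matrix must have unit diagonal")
  if (anyDuplicated(rownames(matrix))) stop("FP names must be unique")
  invisible(matrix)
}

#' Enumerate all feasible N-tuple palettes
#'
#' Finds every N-subset of the FPs whose pairwise cosine similarities all
#' fall below the resolvability threshold, honouring include/exclude
#' constraints, and returns them sorted by ascending objective (sum of
#' pairwise similarities), ties broken lexicographically by member names.
#' The search is a depth-first walk of the compatibility graph that prunes
#' any branch containing an infeasible pair, so it is exhaustive — results
#' equal brute force over all \code{choose(k, n)} subsets.
#'
#' @param matrix Named symmetric similarity matrix with unit diagonal
#'   (e.g. from \code{\link{pairwise_similarity_matrix}} on a library).
#' @param query A \code{\link{palette_query}}.
#' @return List of \code{\link{palette_solution}} objects (possibly empty;
#'   an unreachable \code{n} is not an error). \code{attr(, "truncated")}
#'   is \code{TRUE} when \code{max_results} cut the sorted list.
#' @export
enumerate_feasible_tuples <- function(matrix, query) {
  check_similarity_matrix(matrix)
  stopifnot(inherits(query, "palette_query"))
  nms <- rownames(matrix)
  missing_inc <- setdiff(query$include, nms)
  if (length(missing_inc))
    stop(sprintf("include FP(s) not in matrix: %s",
                 paste(missing_inc, collapse = ", ")))
  compat <- if (query$strict) matrix < query$threshold
            else matrix <= query$threshold
  diag(compat) <- TRUE
  inc_idx <- match(query$include, nms)
  # infeasible include set: no solutions at all
  if (length(inc_idx) > 1 &&
      !all(compat[inc_idx, inc_idx][upper.tri(diag(length(inc_idx)))]))
    return(structure(list(), truncated = FALSE))
  eligible <- setdiff(seq_along(nms), c(inc_idx, match(query$exclude, nms,
                                                       nomatch = 0L)))
  # candidates must be compatible with every forced member
  if (length(inc_idx))
    eligible <- eligible[vapply(eligible,
                                function(j) all(compat[j, inc_idx]), TRUE)]
  need <- query$n - length(inc_idx)
  sets <- list()
  if (need == 0) {
    sets <- list(inc_idx)
  } else if (length(eligible) >= need) {
    dfs <- function(chosen, pool) {
      if (length(chosen) == query$n) {
        sets[[length(sets) + 1L]] <<- chosen
        return(invisible())
      }
      remaining <- query$n - length(chosen)
      while (length(pool) >= remaining) {
        j <- pool[1]
        pool <- pool[-1]
        if (all(compat[j, chosen])) {
          dfs(c(chosen, j), pool[compat[pool, j]])
        }
      }
      invisible()
    }
    dfs(inc_idx, eligible)
  }
  sols <- lapply(sets, function(idx) {
    idx <- sort(idx)
    palette_solution(nms[idx], matrix[idx, idx, drop = FALSE],
                     threshold = query$threshold, strict = query$strict)
  })
  obj <- vapply(sols, `[[`, 0, "objective")
  key <- vapply(sols, function(s) paste(sort(s$fp_names), collapse = "\r"), "")
  ord <- order(obj, key)
  sols <- sols[ord]
  truncated <- length(sols) > query$max_results
  if (truncated) sols <- sols[seq_len(query$max_results)]
  structure(sols, truncated = truncated)
}

#' Best (minimum-sum) feasible N-tuple
#'
#' The palette whose members are pairwise resolvable and whose sum of
#' pairwise cosine similarities is minimal — the most mutually
#' distinguishable N-FP choice.
#'
#' @inheritParams enumerate_feasible_tuples
#' @return A \code{\link{palette_solution}}, or \code{NULL} when no feasible
#'   tuple exists.
#' @export
optimal_ntuple <- function(matrix, query) {
  sols <- enumerate_feasible_tuples(matrix, query)
  if (!length(sols)) NULL else sols[[1]]
}

#' Collapse near-duplicate FPs before the tuple search
#'
#' Groups FPs into connected components of the "similarity at or above
#' threshold" graph and keeps the earliest-listed member of each component.
#' When two spectra are nearly identical only one can ever appear in a
#' feasible palette, so dropping the rest shrinks the search; the step is an
#' optional optimisation (off by default in the pipeline) because it can
#' silently remove user-requested FPs.
#'
#' @param matrix Named symmetric similarity matrix.
#' @param threshold Duplicate cutoff (pairs \code{>= threshold} conflict).
#' @return The reduced matrix (representatives only, original order).
#' @export
dedupe_prefilter <- function(matrix, threshold = 0.9) {
  check_similarity_matrix(matrix)
  k <- nrow(matrix)
  adj <- matrix >= threshold
  diag(adj) <- FALSE
  comp <- integer(k)          # connected components by BFS
  cur <- 0L
  for (i in seq_len(k)) {
    if (comp[i] == 0L) {
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(adj[v, ] & comp == 0L)
        comp[nb] <- cur
        queue <- c(queue, nb)
      }
    }
  }
  keep <- vapply(seq_len(max(comp)), function(g) min(which(comp == g)), 1L)
  keep <- sort(keep)
  matrix[keep, keep, drop = FALSE]
}

#' Export a palette report (heatmap, spectra, JSON)
#'
#' Writes a pairwise-similarity heatmap PNG, an overlaid reference-spectra
#' line plot PNG (unit-normalised so shapes are comparable), and a JSON
#' record of member names, submatrix and objective.
#'
#' @param solution A \code{\link{palette_solution}}.
#' @param library A \code{\link{reference_library}} containing every member.
#' @param dir Output directory (created if absent).
#' @param prefix File-name prefix (default \code{"palette"}).
#' @return Named character vector of the three paths written, invisibly.
#' @export
export_palette_report <- function(solution, library, dir,
                                  prefix = "palette") {
  stopifnot(inherits(solution, "palette_solution"),
            inherits(library, "reference_library"))
  if (!length(solution$fp_names)) stop("empty palette solution")
  unknown <- setdiff(solution$fp_names, fp_names(library))
  if (length(unknown))
    stop(sprintf("FP(s) not in library: %s", paste(unknown, collapse = ", ")))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  heat_path <- file.path(dir, paste0(prefix, "_heatmap.png"))
  spec_path <- file.path(dir, paste0(prefix, "_spectra.png"))
  json_path <- file.path(dir, paste0(prefix, ".json"))

  k <- length(solution$fp_names)
  grDevices::png(heat_path, width = 640, height = 560)
  old <- graphics::par(mar = c(7, 7, 3, 5))
  graphics::image(seq_len(k), seq_len(k),
                  t(solution$submatrix[k:1, , drop = FALSE]),
                  zlim = c(0, 1), axes = FALSE, xlab = "", ylab = "",
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
                  main = sprintf("Pairwise cosine similarity (objective %.3f)",
                                 solution$objective))
  graphics::axis(1, seq_len(k), solution$fp_names, las = 2, cex.axis = 0.8)
  graphics::axis(2, seq_len(k), rev(solution$fp_names), las = 2,
                 cex.axis = 0.8)
  for (i in seq_len(k)) for (j in seq_len(k))
    graphics::text(j, k - i + 1, sprintf("%.2f", solution$submatrix[i, j]),
                   cex = 0.7)
  graphics::par(old)
  grDevices::dev.off()

  m <- library_matrix(library)[solution$fp_names, , drop = FALSE]
  m <- t(apply(m, 1, normalize_spectrum))
  grDevices::png(spec_path, width = 800, height = 480)
  graphics::matplot(t(m), type = "l", lty = 1, lwd = 2,
                    col = grDevices::hcl.colors(k, "Dark 3"),
                    xlab = "channel", ylab = "normalized intensity",
                    main = "Palette reference spectra")
  graphics::legend("topright", legend = solution$fp_names, lty = 1, lwd = 2,
                   col = grDevices::hcl.colors(k, "Dark 3"), cex = 0.8)
  grDevices::dev.off()

  jsonlite::write_json(list(fp_names = solution$fp_names,
                            objective = solution$objective,
                            feasible = solution$feasible,
                            submatrix = solution$submatrix),
                       json_path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(c(heatmap = heat_path, spectra = spec_path, json = json_path))
}

#' Seven-FP green-panel similarity fixture
#'
#' A 7x7 pairwise cosine-similarity matrix reproducing the qualitative
#' structure reported for a panel of seven green-emitting FPs: four FPs
#' share one emission pattern (pairwise similarity 0.95-0.99), two share a
#' second, nearly identical pattern (similarity 1.00), cross-pattern pairs
#' fall at 0.81-0.87, and mT-Sapphire — the spectral outlier with a large
#' Stokes shift — sits at 0.15-0.58 against everything else. Pairs within a
#' category are set to the midpoint of its range. Under the 0.9 threshold
#' this structure admits exactly 8 resolvable 3-tuples and no 4-tuples or
#' larger: a feasible palette can pick at most one FP per pattern.
#'
#' @return A 7x7 named symmetric matrix.
#' @export
green_panel_matrix <- function() {
  pattern1 <- c("EGFP", "mUkG", "mAvicFP1", "Clover")
  pattern2 <- c("mNeonGreen", "mClover3")
  outlier <- "mT-Sapphire"
  nms <- c(pattern1, pattern2, outlier)
  m <- matrix(NA_real_, 7, 7, dimnames = list(nms, nms))
  within1 <- mean(c(0.95, 0.99))
  within2 <- 1.00
  cross <- mean(c(0.81, 0.87))
  sapphire <- mean(c(0.15, 0.58))
  m[pattern1, pattern1] <- within1
  m[pattern2, pattern2] <- within2
  m[pattern1, pattern2] <- cross
  m[pattern2, pattern1] <- cross
  m[outlier, ] <- sapphire
  m[, outlier] <- sapphire
  diag(m) <- 1
  m
}
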