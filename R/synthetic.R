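#' Identity genome
#'
#' The unrearranged circular gene order `1, 2, ..., n`; signed genomes get
#' all-positive orientations. This is the common ancestor from which the
#' randomization experiments start.
#'
#' @param n gene count, at least 3.
#' @param signed logical.
#' @return A `genome`.
#' @export
identity_genome <- function(n, signed = FALSE) {
  if (n < 3L) stop("circular genomes need at least 3 genes")
  genome(seq_len(as.integer(n)), signed = isTRUE(signed))
}

#' Randomize a genome by random gene-position swaps
#'
#' Applies `swaps` successive rearrangements, each exchanging the genes at
#' two distinct positions chosen uniformly at random; a single swap creates
#' at most four new breakpoints, so `d(g, result) <= 4 * swaps`. For signed
#' genomes the orientation of each swapped gene is re-drawn uniformly from
#' {+, -} (a swap may therefore restore a sign to its previous value). This
#' is a generic scrambling device, not a model of any particular biological
#' rearrangement process.
#'
#' Randomness comes from R's global RNG; call `set.seed()` (or use the
#' experiment drivers, which manage per-replicate seeds) for
#' reproducibility. Per swap the draw order is: one `sample.int(n, 2)` for
#' the positions, then -- signed genomes only -- one `sample(c(1,-1), 2,
#' replace = TRUE)` for the two new orientations.
#'
#' @param g a `genome`.
#' @param swaps non-negative integer number of swaps.
#' @return A `genome` on the same gene set and signedness.
#' @export
swap_randomize <- function(g, swaps) {
  stopifnot(is_genome(g))
  swaps <- as.integer(swaps)
  if (swaps < 0L) stop("`swaps` must be non-negative")
  ord <- g$order; sg <- g$signs; n <- g$n
  for (i in seq_len(swaps)) {
    ij <- sample.int(n, 2L)
    ord[ij] <- ord[rev(ij)]
    if (!is.null(sg)) sg[ij] <- sample(c(1L, -1L), 2L, replace = TRUE)
  }
  structure(list(order = ord, signs = sg, n = n), class = "genome")
}

#' Swaps-per-100-genes to absolute swap count
#'
#' Experiment drivers express randomization intensity per 100 genes so
#' that trajectories for different `n` are comparable; internally swap
#' counts are absolute.
#'
#' @param s_per_100 swaps per 100 genes.
#' @param n gene count.
#' @return `round(s_per_100 * n / 100)` as integer.
#' @export
swaps_absolute <- function(s_per_100, n) as.integer(round(s_per_100 * n / 100))

#' Uniform random circular genome
#'
#' Draws a uniform random linear permutation of `1..n` and reads it
#' circularly; every circular equivalence class has the same number (2n) of
#' linear representatives, so the draw is uniform over classes. Signed
#' genomes additionally receive independent uniform orientations.
#'
#' Uses R's global RNG. Draw order: one `sample.int(n)`, then (signed) one
#' `sample(c(1,-1), n, replace = TRUE)`.
#'
#' @param n gene count, at least 3.
#' @param signed logical.
#' @return A `genome`.
#' @export
uniform_random_genome <- function(n, signed = FALSE) {
  if (n < 3L) stop("circular genomes need at least 3 genes")
  n <- as.integer(n)
  ord <- sample.int(n)
  sg <- if (isTRUE(signed)) sample(c(1L, -1L), n, replace = TRUE) else NULL
  structure(list(order = ord, signs = sg, n = n), class = "genome")
}

#' Shared-adjacency statistics of independent uniform genome pairs
#'
#' Samples `reps` independent pairs of uniform random genomes and records
#' the number of adjacencies each pair shares. For large `n` this count is
#' approximately Poisson: rate 2 for unsigned genomes and 1/2 for signed
#' ones (a random gene pair must also agree in relative orientation), which
#' is why the normalized breakpoint distance between random genomes tends
#' to 1 in both cases.
#'
#' @param n gene count.
#' @param signed logical.
#' @param reps number of independent pairs, at least 1.
#' @return A list with class `adjacency_count_summary`: `reps`, `mean`,
#'   `variance` (sample variance), and `counts` (the raw per-pair counts).
#' @export
shared_adjacency_stats <- function(n, signed = FALSE, reps) {
  reps <- as.integer(reps)
  if (reps < 1L) stop("`reps` must be at least 1")
  counts <- integer(reps)
  for (i in seq_len(reps)) {
    a <- uniform_random_genome(n, signed)
    b <- uniform_random_genome(n, signed)
    counts[i] <- sum(adjacencies(a)$codes %in% adjacencies(b)$codes)
  }
  structure(list(reps = reps, mean = mean(counts),
                 variance = if (reps > 1L) stats::var(counts) else 0,
                 counts = counts),
            class = "adjacency_count_summary")
}

#' @export
print.adjacency_count_summary <- function(x, ...) {
  cat(sprintf("shared adjacencies over %d pairs: mean %.4f, variance %.4f\n",
              x$reps, x$mean, x$variance))
  invisible(x)
}
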