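#' A breakpoint k-median instance
#'
#' Bundles k >= 3 circular genomes on the same gene set and signedness. The
#' k-median problem asks for a genome M minimizing the median sum
#' `sum_i d(M, A_i)` of breakpoint distances to the inputs.
#'
#' @param genomes a list of at least 3 `genome` objects sharing `n` and
#'   signedness.
#' @return An object of class `median_instance` with fields `genomes`, `k`,
#'   `n`, `signed`.
#' @export
median_instance <- function(genomes) {
  if (is_genome(genomes)) stop("`genomes` must be a list of at least 3 genomes")
  if (!is.list(genomes) || length(genomes) < 3L)
    stop("a median instance needs k >= 3 genomes")
  if (!all(vapply(genomes, is_genome, logical(1))))
    stop("all elements must be `genome` objects")
  n <- genomes[[1L]]$n
  sgn <- is_signed(genomes[[1L]])
  for (g in genomes[-1L]) {
    if (g$n != n) stop("all genomes must share the same gene count")
    if (is_signed(g) != sgn) stop("all genomes must share the same signedness")
  }
  structure(list(genomes = genomes, k = length(genomes), n = n, signed = sgn),
            class = "median_instance")
}

#' @export
print.median_instance <- function(x, ...) {
  cat(sprintf("breakpoint median instance: k = %d %s genomes, n = %d\n",
              x$k, if (x$signed) "signed" else "unsigned", x$n))
  invisible(x)
}

# tour encoding of a genome on the median graph's vertices:
# unsigned -> the gene order itself; signed -> the extremity walk, each gene
# contributing (tail, head) when oriented + and (head, tail) when -.
genome_tour <- function(g) {
  if (!is_signed(g)) return(g$order)
  first <- ifelse(g$signs > 0L, 2L * g$order - 1L, 2L * g$order)
  second <- ifelse(g$signs > 0L, 2L * g$order, 2L * g$order - 1L)
  as.integer(rbind(first, second))
}

#' Build the weighted graph of the TSP reduction
#'
#' For unsigned genomes the graph is complete on the n genes; for each gene
#' pair `xy`, `v(xy)` counts the input genomes in which x and y are
#' adjacent and the edge weight is `w(xy) = k - v(xy)`, so a minimum-weight
#' Hamilton cycle is a median genome and its weight is the median sum. For
#' signed genomes the graph has the 2n gene extremities as vertices
#' (`tail(g) = 2g - 1`, `head(g) = 2g`); the n intra-gene (tail, head)
#' edges carry weight 0 and are structurally forced into every tour, and
#' extremity-pair adjacency edges are weighted `k - v` as before, so tours
#' alternate gene traversals and adjacencies.
#'
#' @param inst a `median_instance`.
#' @return An object of class `median_graph`: `weights` (N x N integer
#'   matrix), `forced` (matrix of forced edges, 0 rows when unsigned),
#'   `n`, `k`, `signed`, `n_vertices`.
#' @export
build_median_graph <- function(inst) {
  stopifnot(inherits(inst, "median_instance"))
  n <- inst$n; k <- inst$k
  N <- if (inst$signed) 2L * n else n
  v <- matrix(0L, N, N)
  for (g in inst$genomes) {
    p <- adjacencies(g)$pairs
    idx <- cbind(p[, 1L], p[, 2L])
    v[idx] <- v[idx] + 1L
    v[idx[, 2:1, drop = FALSE]] <- v[idx[, 2:1, drop = FALSE]] + 1L
  }
  w <- k - v
  diag(w) <- 0L
  if (inst$signed) {
    forced <- cbind(2L * seq_len(n) - 1L, 2L * seq_len(n))
    w[forced] <- 0L
    w[forced[, 2:1, drop = FALSE]] <- 0L
  } else {
    forced <- matrix(integer(0), 0L, 2L)
  }
  structure(list(weights = w, forced = forced, n = n, k = k,
                 signed = inst$signed, n_vertices = N),
            class = "median_graph")
}

check_tour <- function(tour, graph) {
  tour <- as.integer(tour)
  N <- graph$n_vertices
  if (length(tour) != N || !identical(sort(tour), seq_len(N)))
    stop("`tour` must visit each of the ", N, " vertices exactly once")
  tour
}

#' Weight of a Hamiltonian tour on a median graph
#'
#' By construction this equals the median sum of the genome the tour
#' decodes to (forced intra-gene edges weigh 0 in the signed case).
#'
#' @param tour integer vector: a Hamiltonian vertex sequence.
#' @param graph a `median_graph`.
#' @return Integer tour weight.
#' @export
tour_weight <- function(tour, graph) {
  tour <- check_tour(tour, graph)
  nxt <- c(tour[-1L], tour[1L])
  sum(graph$weights[cbind(tour, nxt)])
}

#' Decode a Hamiltonian tour into a genome
#'
#' Unsigned graphs: the tour vertex sequence is the gene order. Signed
#' graphs: the tour must traverse the two extremities of each gene
#' consecutively (guaranteed when the forced edges are respected); a gene
#' entered at its tail reads +, entered at its head reads -.
#'
#' @inheritParams tour_weight
#' @return A `genome` in canonical form.
#' @export
decode_tour <- function(tour, graph) {
  tour <- check_tour(tour, graph)
  if (!graph$signed) return(canonical_form(genome(tour)))
  N <- graph$n_vertices
  gene <- (tour + 1L) %/% 2L
  # rotate so the walk starts at the first extremity of a gene traversal
  if (gene[1L] == gene[N]) tour <- c(tour[N], tour[-N])
  gene <- (tour + 1L) %/% 2L
  firsts <- gene[seq(1L, N, by = 2L)]
  seconds <- gene[seq(2L, N, by = 2L)]
  if (!identical(firsts, seconds))
    stop("signed tour does not alternate gene traversals and adjacencies ",
         "(a forced intra-gene edge is missing)")
  signs <- ifelse(tour[seq(1L, N, by = 2L)] %% 2L == 1L, 1L, -1L)
  canonical_form(genome(firsts, signs = signs))
}

#' Export a median graph in TSPLIB format
#'
#' Writes an `EDGE_WEIGHT_TYPE: EXPLICIT` / `FULL_MATRIX` instance with
#' exact integer weights, plus a `FIXED_EDGES_SECTION` for the forced
#' intra-gene edges of signed instances, for use with external TSP solvers.
#'
#' @param graph a `median_graph`.
#' @param path output file.
#' @param name instance name written to the header.
#' @return The path, invisibly.
#' @export
write_tsplib <- function(graph, path, name = "breakpoint_median") {
  stopifnot(inherits(graph, "median_graph"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(sprintf("NAME: %s", name),
               "TYPE: TSP",
               sprintf("COMMENT: breakpoint median reduction, k = %d, n = %d%s",
                       graph$k, graph$n, if (graph$signed) ", signed" else ""),
               sprintf("DIMENSION: %d", graph$n_vertices),
               "EDGE_WEIGHT_TYPE: EXPLICIT",
               "EDGE_WEIGHT_FORMAT: FULL_MATRIX",
               "EDGE_WEIGHT_SECTION"), con)
  apply(graph$weights, 1L, function(r) writeLines(paste(r, collapse = " "), con))
  if (nrow(graph$forced) > 0L) {
    writeLines("FIXED_EDGES_SECTION", con)
    apply(graph$forced, 1L, function(e) writeLines(paste(e, collapse = " "), con))
    writeLines("-1", con)
  }
  writeLines("EOF", con)
  invisible(path)
}

new_median_solution <- function(genome, inst, certified, seed, lower_bound,
                                mode, nodes) {
  d <- vapply(inst$genomes, function(a) breakpoint_distance(genome, a), integer(1))
  structure(list(genome = genome, median_sum = sum(d),
                 per_input_distances = d, certified = certified,
                 seed = seed, lower_bound = lower_bound, mode = mode,
                 nodes = nodes),
            class = "median_solution")
}

#' @export
print.median_solution <- function(x, ...) {
  cat(sprintf("median solution: sum %d (%s), per-input distances %s\n",
              x$median_sum, if (x$certified) "certified optimal" else
                sprintf("heuristic, lower bound %s", format(x$lower_bound)),
              paste(x$per_input_distances, collapse = " ")))
  invisible(x)
}

#' Solve a breakpoint median instance through the TSP reduction
#'
#' Builds the weighted median graph and finds a minimum-weight Hamiltonian
#' cycle. `mode = "exact"` runs a branch-and-bound search with Held-Karp
#' 1-tree Lagrangian lower bounds and returns a certified optimum or fails
#' explicitly when the node/time budget is exhausted (never a silent
#' fallback). `mode = "heuristic"` returns the best of the 2-opt-improved
#' input tours together with a certified integer lower bound; `certified`
#' is `TRUE` only when the two coincide.
#'
#' `seed` controls sampling over alternative optima: it drives a random
#' relabeling of the graph vertices and an infinitesimal random perturbation
#' of the edge weights (total perturbation along any tour below 0.05, far
#' under the integer weight resolution, so optimality statements always
#' refer to the exact integer instance). The perturbation steers spanning
#' tree, local search and branching tie-breaks, so repeated calls with
#' varied seeds reach different co-optimal tours -- sampling the optimum
#' set in the same spirit as re-seeding an external TSP solver.
#'
#' @param inst a `median_instance`.
#' @param seed integer seed for tie-break randomization; `NULL` uses the
#'   current RNG state.
#' @param mode `"exact"` or `"heuristic"`.
#' @param time_limit seconds allowed for the exact search.
#' @param node_limit branch-and-bound node budget.
#' @return A `median_solution`: `genome` (canonical), `median_sum`,
#'   `per_input_distances`, `certified`, `lower_bound`, `seed`, `mode`,
#'   `nodes`.
#' @examples
#' set.seed(1)
#' gs <- replicate(3, swap_randomize(identity_genome(20), 60), simplify = FALSE)
#' solve_median_tsp(median_instance(gs), seed = 7)
#' @export
solve_median_tsp <- function(inst, seed = NULL, mode = c("exact", "heuristic"),
                             time_limit = 120, node_limit = 5e6) {
  mode <- match.arg(mode)
  stopifnot(inherits(inst, "median_instance"))
  graph <- build_median_graph(inst)
  N <- graph$n_vertices
  if (!is.null(seed)) set.seed(as.integer(seed))

  # seed-derived random gene relabeling (extremity pairs move together in
  # the signed case, so forced edges stay intra-gene)
  gperm <- sample.int(graph$n)
  vperm <- if (graph$signed) {
    p <- integer(N)
    p[2L * seq_len(graph$n) - 1L] <- 2L * gperm - 1L
    p[2L * seq_len(graph$n)] <- 2L * gperm
    p
  } else gperm
  Wp <- matrix(0, N, N)
  Wp[vperm, vperm] <- graph$weights

  # symmetric tie-breaking perturbation; any tour accumulates < 0.05 total,
  # so integer weights are recoverable by rounding and the incumbent's
  # integer cost can prune nodes a full unit above the Lagrangian bound
  int_slack <- 0.05
  pert <- matrix(0, N, N)
  ut <- upper.tri(pert)
  pert[ut] <- stats::runif(sum(ut)) * (int_slack / N)
  pert <- pert + t(pert)
  forced_p <- graph$forced
  if (nrow(forced_p) > 0L) {
    forced_p <- cbind(vperm[graph$forced[, 1L]], vperm[graph$forced[, 2L]])
    pert[forced_p] <- 0
    pert[forced_p[, 2:1, drop = FALSE]] <- 0
  }
  Wd <- Wp + pert

  init <- t(vapply(inst$genomes, function(g) vperm[genome_tour(g)], integer(N)))
  init <- init[sample.int(nrow(init)), , drop = FALSE]  # no presentation-order bias

  res <- .solve_tsp_bb(Wd, forced_p, init, mode == "exact",
                       node_limit, time_limit,
                       rootIters = max(200L, 5L * N), childIters = 50L,
                       intSlack = int_slack)
  if (mode == "exact" && isTRUE(res$aborted))
    stop("exact median solve exceeded its budget (", res$nodes,
         " nodes); re-run with a larger `time_limit`/`node_limit` or use ",
         "mode = \"heuristic\"")

  tour <- match(res$tour, vperm)  # back to original vertex labels
  g <- decode_tour(tour, graph)
  lb <- if (mode == "exact") NA_integer_ else
    max(0L, as.integer(ceiling(res$bound - int_slack - 1e-9)))
  sol <- new_median_solution(g, inst, certified = mode == "exact",
                             seed = seed, lower_bound = lb, mode = mode,
                             nodes = res$nodes)
  if (mode == "heuristic") {
    sol$certified <- !is.na(lb) && sol$median_sum == lb
    if (sol$certified) sol$lower_bound <- sol$median_sum
  } else {
    sol$lower_bound <- sol$median_sum
  }
  sol
}

# all linear representatives of circular classes, gene 1 first, reflection
# removed by requiring order[2] < order[n]
unsigned_class_orders <- function(n) {
  perms <- permutations_of(seq(2L, n))
  keep <- vapply(perms, function(p) p[1L] < p[n - 1L], logical(1))
  lapply(perms[keep], function(p) c(1L, p))
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    rest <- permutations_of(x[-i])
    out <- c(out, lapply(rest, function(p) c(x[i], p)))
  }
  out
}

#' Exhaustive breakpoint-median solver (validation oracle)
#'
#' Enumerates every circular genome class on n genes -- `(n-1)!/2` unsigned
#' classes, `2^(n-1) (n-1)!` signed classes -- and returns all genomes
#' attaining the minimum median sum. Exponential; intended as an
#' independent oracle for validating the TSP-reduction solver on tiny
#' instances.
#'
#' @param inst a `median_instance` with `n <= 8` (unsigned) or `n <= 5`
#'   (signed).
#' @return A list: `solutions` (list of canonical genomes, all optima),
#'   `median_sum`, `count`.
#' @export
solve_median_bruteforce <- function(inst) {
  stopifnot(inherits(inst, "median_instance"))
  n <- inst$n
  if (!inst$signed && n > 8L) stop("brute force limited to n <= 8 unsigned genomes")
  if (inst$signed && n > 5L) stop("brute force limited to n <= 5 signed genomes")
  input_adj <- lapply(inst$genomes, function(g) adjacencies(g)$codes)
  score <- function(g) {
    cg <- adjacencies(g)$codes
    sum(vapply(input_adj, function(a) n - sum(cg %in% a), integer(1)))
  }
  best <- Inf; sols <- list()
  consider <- function(g) {
    s <- score(g)
    if (s < best) { best <<- s; sols <<- list(g) }
    else if (s == best) sols <<- c(sols, list(g))
  }
  if (!inst$signed) {
    for (ord in unsigned_class_orders(n))
      consider(structure(list(order = ord, signs = NULL, n = n), class = "genome"))
  } else {
    seen <- new.env(hash = TRUE)
    sign_rows <- as.matrix(expand.grid(rep(list(c(1L, -1L)), n)))
    for (ord in lapply(permutations_of(seq(2L, n)), function(p) c(1L, p))) {
      for (r in seq_len(nrow(sign_rows))) {
        g <- canonical_form(structure(list(order = ord,
                                           signs = as.integer(sign_rows[r, ]),
                                           n = n), class = "genome"))
        key <- genome_key(g)
        if (!is.null(seen[[key]])) next
        seen[[key]] <- TRUE
        consider(g)
      }
    }
  }
  list(solutions = lapply(sols, canonical_form),
       median_sum = as.integer(best), count = length(sols))
}

#' Median sum by Held-Karp dynamic programming (cross-check)
#'
#' Computes the exact minimum median sum of an unsigned instance with a
#' bitmask dynamic program over vertex subsets -- an implementation
#' independent of the branch-and-bound search, usable up to n = 13.
#'
#' @param inst an unsigned `median_instance` with `n <= 13`.
#' @return Integer minimum median sum.
#' @export
median_sum_held_karp <- function(inst) {
  stopifnot(inherits(inst, "median_instance"))
  if (inst$signed) stop("the dynamic-programming cross-check handles unsigned instances only")
  if (inst$n > 13L) stop("Held-Karp cross-check limited to n <= 13")
  graph <- build_median_graph(inst)
  res <- .held_karp_tsp(graph$weights + 0)
  as.integer(round(res$cost))
}

#' Sample alternative optimal medians
#'
#' Solves the same instance repeatedly under consecutive tie-breaking seeds
#' (`base_seed`, `base_seed + 1`, ...), so equal-weight optima are reached
#' in varied order. All returned solutions carry the same minimal median
#' sum; duplicates are permitted, since independently sampled optima may
#' coincide.
#'
#' @param inst a `median_instance`.
#' @param m number of solutions to sample.
#' @param base_seed integer seed of the first solve.
#' @param ... passed to [solve_median_tsp()].
#' @return A list of `m` `median_solution` objects.
#' @export
sample_medians <- function(inst, m, base_seed, ...) {
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be at least 1")
  sols <- lapply(seq_len(m) - 1L,
                 function(i) solve_median_tsp(inst, seed = base_seed + i, ...))
  sums <- vapply(sols, `[[`, integer(1), "median_sum")
  if (length(unique(sums)) > 1L)
    stop("sampled solutions disagree on the median sum; solver inconsistency")
  sols
}

#' Classify a median as a corner or a middle solution
#'
#' A solution approximately equidistant from all inputs -- normalized
#' distance spread `(max_i d(M, A_i) - min_i d(M, A_i)) / n` at most `tau`
#' -- is a MIDDLE (compromise) median; otherwise it is a CORNER median
#' attributed to its nearest input (smallest index on ties). The default
#' `tau = 0.05` sits far from both regimes observed for scrambled inputs:
#' corner solutions have spread near 1, middle solutions near 0.
#'
#' @param sol a `median_solution` (or a `genome`).
#' @param inst the `median_instance` it solves.
#' @param tau normalized spread below which a solution counts as middle.
#' @param eps neighbourhood radius used for the `near_input` flag.
#' @return A list of class `median_classification`: `label` ("CORNER" or
#'   "MIDDLE"), `corner` (input index, `NA` for middle),
#'   `nearest_input_distance` (normalized), `spread`, `near_input`
#'   (`TRUE` when the solution lies in the eps-neighbourhood of an input).
#' @export
classify_median <- function(sol, inst, tau = 0.05, eps = 0.1) {
  if (!is.numeric(tau) || tau <= 0 || tau >= 1) stop("`tau` must lie in (0, 1)")
  if (!is.numeric(eps) || eps <= 0 || eps >= 1) stop("`eps` must lie in (0, 1)")
  d <- if (inherits(sol, "median_solution")) sol$per_input_distances
       else vapply(inst$genomes, function(a) breakpoint_distance(sol, a), integer(1))
  n <- inst$n
  spread <- (max(d) - min(d)) / n
  middle <- spread <= tau
  structure(list(label = if (middle) "MIDDLE" else "CORNER",
                 corner = if (middle) NA_integer_ else which.min(d),
                 nearest_input_distance = min(d) / n,
                 spread = spread,
                 near_input = min(d) / n < eps),
            class = "median_classification")
}

#' @export
print.median_classification <- function(x, ...) {
  cat(sprintf("%s%s: nearest input at %.3f, spread %.3f\n", x$label,
              if (is.na(x$corner)) "" else paste0("(", x$corner, ")"),
              x$nearest_input_distance, x$spread))
  invisible(x)
}

#' Mean pairwise normalized distance among solutions
#'
#' Average normalized breakpoint distance over all unordered pairs of
#' solution genomes; 0 for a single solution.
#'
#' @param solutions non-empty list of `median_solution` (or `genome`)
#'   objects.
#' @return Numeric in `[0, 1]`.
#' @export
mean_pairwise_distance <- function(solutions) {
  if (length(solutions) == 0L) stop("`solutions` must not be empty")
  gs <- lapply(solutions, function(s)
    if (inherits(s, "median_solution")) s$genome else s)
  m <- length(gs)
  if (m == 1L) return(0)
  tot <- 0
  for (i in seq_len(m - 1L))
    for (j in seq(i + 1L, m))
      tot <- tot + normalized_distance(gs[[i]], gs[[j]])
  tot / choose(m, 2L)
}
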