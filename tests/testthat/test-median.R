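test_that("median graph weights count adjacency support (w = k - v)", {
  id <- identity_genome(5)
  inst <- median_instance(list(id, id, id))
  g <- build_median_graph(inst)
  adj <- adjacencies(id)$pairs
  expect_true(all(g$weights[adj] == 0L))      # shared by all 3 inputs
  off <- g$weights
  off[adj] <- NA; off[adj[, 2:1]] <- NA; diag(off) <- NA
  expect_true(all(off[!is.na(off)] == 3L))    # v = 0 elsewhere

  # an adjacency present in exactly one of three inputs weighs k - 1 = 2
  inst2 <- median_instance(list(genome(c(1, 2, 3, 4, 5)),
                                genome(c(1, 3, 5, 2, 4)),
                                genome(c(1, 4, 2, 5, 3))))
  g2 <- build_median_graph(inst2)
  expect_identical(g2$weights[1, 2], 2L)  # {1,2} only in the first input

  # k = 5, pair in no input
  inst5 <- median_instance(replicate(5, genome(c(1, 2, 3, 4, 5)), simplify = FALSE))
  expect_identical(build_median_graph(inst5)$weights[1, 3], 5L)

  # signed: 2n vertices, forced intra-gene edges at weight 0
  sg <- median_instance(replicate(3, identity_genome(4, signed = TRUE),
                                  simplify = FALSE))
  gs <- build_median_graph(sg)
  expect_identical(gs$n_vertices, 8L)
  expect_identical(nrow(gs$forced), 4L)
  expect_true(all(gs$weights[gs$forced] == 0L))
})

test_that("tour weight equals the decoded genome's median sum", {
  set.seed(23)
  for (trial in 1:60) {
    n <- sample(4:10, 1)
    k <- sample(3:5, 1)
    signed <- trial %% 2 == 0
    inst <- random_instance(n, k, signed)
    graph <- build_median_graph(inst)
    tour <- if (signed) bpmedian:::genome_tour(random_genome(n, TRUE))
            else sample.int(n)
    M <- decode_tour(tour, graph)
    expect_identical(tour_weight(tour, graph),
                     sum(vapply(inst$genomes,
                                function(a) breakpoint_distance(M, a),
                                integer(1))))
  }
  # identity tour on identical inputs has weight 0
  inst <- median_instance(replicate(3, identity_genome(6), simplify = FALSE))
  expect_identical(tour_weight(1:6, build_median_graph(inst)), 0L)
})

test_that("tour decoding recovers orders and orientations", {
  u <- build_median_graph(median_instance(replicate(3, identity_genome(5),
                                                    simplify = FALSE)))
  expect_true(genomes_equal(decode_tour(c(1, 2, 3, 4, 5), u), genome(1:5)))
  s <- build_median_graph(median_instance(replicate(3, identity_genome(3, signed = TRUE),
                                                    simplify = FALSE)))
  # t1 h1 t2 h2 t3 h3 reads all-forward
  expect_true(genomes_equal(decode_tour(c(1, 2, 3, 4, 5, 6), s),
                            genome(1:3, signed = TRUE)))
  # t1 h1 h2 t2 t3 h3 reads gene 2 backwards
  expect_true(genomes_equal(decode_tour(c(1, 2, 4, 3, 5, 6), s),
                            genome(c(1, -2, 3))))
  # a walk splitting a gene's extremities is rejected
  expect_error(decode_tour(c(1, 3, 2, 4, 5, 6), s), "alternate")
  expect_error(decode_tour(c(1, 2, 3), u), "exactly once")
})

test_that("brute force handles degenerate instances as expected", {
  id <- identity_genome(5)
  bf <- solve_median_bruteforce(median_instance(list(id, id, id)))
  expect_identical(bf$median_sum, 0L)
  expect_identical(bf$count, 1L)
  expect_true(genomes_equal(bf$solutions[[1]], id))

  set.seed(9)
  other <- random_genome(6)
  a <- random_genome(6)
  inst <- median_instance(list(a, a, other))
  bf2 <- solve_median_bruteforce(inst)
  expect_identical(bf2$median_sum, breakpoint_distance(a, other))
  expect_true(any(vapply(bf2$solutions, genomes_equal, logical(1), b = a)))
  expect_error(solve_median_bruteforce(random_instance(9)), "n <= 8")
})

test_that("the TSP solver certifies the brute-force optimum on random instances", {
  set.seed(77)
  for (trial in 1:12) {
    inst <- random_instance(sample(5:7, 1))
    bf <- solve_median_bruteforce(inst)
    sol <- solve_median_tsp(inst, seed = trial)
    expect_identical(sol$median_sum, bf$median_sum)
    expect_true(sol$certified)
    expect_identical(sol$median_sum, sum(sol$per_input_distances))
    expect_identical(median_sum_held_karp(inst), bf$median_sum)
  }
  for (trial in 1:6) {
    inst <- random_instance(sample(4:5, 1), signed = TRUE)
    bf <- solve_median_bruteforce(inst)
    expect_identical(solve_median_tsp(inst, seed = trial)$median_sum,
                     bf$median_sum)
  }
})

test_that("median sum never exceeds the best single-input candidate", {
  set.seed(13)
  for (trial in 1:10) {
    inst <- random_instance(sample(8:20, 1), k = sample(3:4, 1),
                            signed = trial %% 2 == 0)
    sol <- solve_median_tsp(inst, seed = trial)
    input_sums <- vapply(seq_len(inst$k), function(i)
      sum(vapply(inst$genomes, breakpoint_distance, integer(1),
                 a = inst$genomes[[i]])), integer(1))
    expect_lte(sol$median_sum, min(input_sums))
  }
})

test_that("an exhausted search budget fails loudly, never silently", {
  set.seed(2)
  inst <- random_instance(30)
  expect_error(solve_median_tsp(inst, seed = 1, node_limit = 0), "budget")
  # heuristic mode reports a bound instead of failing
  h <- solve_median_tsp(inst, seed = 1, mode = "heuristic")
  expect_gte(h$median_sum, h$lower_bound)
  if (h$certified) expect_identical(h$median_sum, h$lower_bound)
  exact <- solve_median_tsp(inst, seed = 1)
  expect_lte(exact$median_sum, h$median_sum)
  expect_gte(exact$median_sum, h$lower_bound)
})

test_that("seed-varied sampling recovers multiple optima when they exist", {
  id <- identity_genome(6)
  sols <- sample_medians(median_instance(list(id, id, id)), 5, base_seed = 4)
  expect_length(sols, 5L)
  expect_true(all(vapply(sols, function(s) genomes_equal(s$genome, id), logical(1))))
  expect_equal(mean_pairwise_distance(sols), 0)

  set.seed(55)
  found_multi <- FALSE
  for (trial in 1:8) {
    inst <- random_instance(7)
    bf <- solve_median_bruteforce(inst)
    sols <- sample_medians(inst, 15, base_seed = trial * 100)
    expect_true(all(vapply(sols, `[[`, integer(1), "median_sum") == bf$median_sum))
    labels <- unique(vapply(sols, function(s) genome_label(s$genome), character(1)))
    bf_labels <- vapply(bf$solutions, genome_label, character(1))
    expect_true(all(labels %in% bf_labels))
    if (bf$count >= 2 && length(labels) >= 2) found_multi <- TRUE
  }
  expect_true(found_multi)
})

test_that("corner/middle classification follows the spread rule", {
  set.seed(66)
  inst <- random_instance(20)
  # the first input genome itself is a corner solution for input 1
  cls <- classify_median(inst$genomes[[1]], inst)
  expect_identical(cls$label, "CORNER")
  expect_identical(cls$corner, 1L)
  expect_identical(cls$nearest_input_distance, 0)
  expect_true(cls$near_input)

  fake <- function(d) structure(list(per_input_distances = d), class = "median_solution")
  mid <- classify_median(fake(c(60L, 61L, 60L)), random_instance(100))
  expect_identical(mid$label, "MIDDLE")
  expect_true(is.na(mid$corner))
  crn <- classify_median(fake(c(5L, 95L, 96L)), random_instance(100))
  expect_identical(crn$label, "CORNER")
  expect_identical(crn$corner, 1L)
  # all-zero distances (identical inputs) pin to MIDDLE by the spread rule
  degenerate <- classify_median(fake(c(0L, 0L, 0L)), random_instance(100))
  expect_identical(degenerate$label, "MIDDLE")
  expect_error(classify_median(fake(c(1L, 2L, 3L)), inst, tau = 0), "tau")
})

test_that("mean pairwise distance averages over unordered pairs", {
  a <- genome(1:6)
  b <- genome(c(1, 3, 2, 4, 5, 6))
  d <- normalized_distance(a, b)
  expect_equal(mean_pairwise_distance(list(a)), 0)
  expect_equal(mean_pairwise_distance(list(a, b)), d)
  expect_equal(mean_pairwise_distance(list(a, a, b)), 2 * d / 3)
  expect_error(mean_pairwise_distance(list()), "empty")
})

test_that("TSPLIB export writes an explicit full matrix", {
  inst <- random_instance(5)
  path <- withr::local_tempfile(fileext = ".tsp")
  write_tsplib(build_median_graph(inst), path)
  lines <- readLines(path)
  expect_true("EDGE_WEIGHT_TYPE: EXPLICIT" %in% lines)
  expect_true("DIMENSION: 5" %in% lines)
  m <- which(lines == "EDGE_WEIGHT_SECTION")
  mat <- do.call(rbind, lapply(lines[(m + 1):(m + 5)],
                               function(l) scan(text = l, quiet = TRUE)))
  expect_identical(dim(mat), c(5L, 5L))
  expect_true(all(mat == round(mat)))
  expect_identical(lines[length(lines)], "EOF")

  sg <- median_instance(replicate(3, identity_genome(3, signed = TRUE),
                                  simplify = FALSE))
  write_tsplib(build_median_graph(sg), path)
  slines <- readLines(path)
  expect_true("FIXED_EDGES_SECTION" %in% slines)
  expect_true("DIMENSION: 6" %in% slines)
})
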