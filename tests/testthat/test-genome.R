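test_that("genome construction validates its input", {
  expect_s3_class(genome(c(2, 1, 3)), "genome")
  expect_error(genome(c(1, 2)), "at least 3")
  expect_error(genome(c(1, 2, 2)), "permutation")
  expect_error(genome(c(1, 2, 5)), "permutation")
  expect_error(genome(c(-1, 2, 3), signs = c(1, 1, 1)), "not both")
  expect_error(genome(1:3, signs = c(1, 1)), "every gene")
  g <- genome(c(-2, 1, 3))
  expect_true(is_signed(g))
  expect_identical(g$order, c(2L, 1L, 3L))
  expect_identical(g$signs, c(-1L, 1L, 1L))
  expect_false(is_signed(genome(1:4)))
  expect_true(is_signed(genome(1:4, signed = TRUE)))
})

test_that("canonical form is invariant under rotation and reflection", {
  id5 <- genome(1:5)
  expect_identical(canonical_form(genome(c(3, 4, 5, 1, 2)))$order, id5$order)
  expect_identical(canonical_form(genome(c(1, 5, 4, 3, 2)))$order, id5$order)
  # a signed class: all 2n representations collapse to one canonical pick
  g <- genome(c(-1, -3, -2))
  expect_true(genomes_equal(g, genome(c(2, 3, 1), signed = TRUE)))
})

test_that("canonical form is idempotent and constant on each orbit", {
  set.seed(41)
  for (trial in 1:30) {
    n <- sample(3:6, 1)
    g <- random_genome(n, signed = trial %% 2 == 0)
    reprs <- orbit_representations(g)
    canon <- lapply(reprs, canonical_form)
    keys <- vapply(canon, function(c)
      paste(c$order, paste(c$signs, collapse = ","), collapse = "|"),
      character(1))
    expect_length(unique(keys), 1L)
    cc <- canonical_form(canon[[1L]])
    expect_identical(cc$order, canon[[1L]]$order)
    expect_identical(cc$signs, canon[[1L]]$signs)
    # the canonical pick is itself a member of the orbit
    expect_true(any(vapply(reprs, function(r)
      identical(r$order, canon[[1L]]$order) &&
        identical(r$signs, canon[[1L]]$signs), logical(1))))
  }
})

test_that("adjacency sets have n pairs with the right degree structure", {
  a <- adjacencies(genome(1:5))
  expect_equal(nrow(a$pairs), 5L)
  expect_setequal(apply(a$pairs, 1, paste, collapse = "-"),
                  c("1-2", "2-3", "3-4", "4-5", "1-5"))
  # any unsigned genome on 3 genes has the unique adjacency set
  for (ord in list(c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))) {
    a3 <- adjacencies(genome(ord))
    expect_setequal(apply(a3$pairs, 1, paste, collapse = "-"),
                    c("1-2", "2-3", "1-3"))
  }
  # signed identity: head(g) joins tail(g+1); extremities t=2g-1, h=2g
  s <- adjacencies(genome(1:3, signed = TRUE))
  expect_setequal(apply(s$pairs, 1, paste, collapse = "-"),
                  c("2-3", "4-5", "1-6"))
  # degree conditions on random genomes
  set.seed(7)
  for (trial in 1:20) {
    n <- sample(3:10, 1)
    sg <- trial %% 2 == 0
    adj <- adjacencies(random_genome(n, sg))
    expect_equal(nrow(adj$pairs), n)
    occ <- table(c(adj$pairs))
    if (sg) expect_true(all(occ == 1L)) else expect_true(all(occ == 2L))
  }
})

test_that("breakpoint distance matches hand-enumerated examples", {
  A <- genome(1:5)
  expect_identical(breakpoint_distance(A, A), 0L)
  # B shares {2,3}, {4,5}, {5,1} with the identity
  B <- genome(c(1, 3, 2, 4, 5))
  expect_identical(breakpoint_distance(A, B), 2L)
  expect_equal(normalized_distance(A, B), 2 / 5)
  # signed: flipping one gene of the identity breaks its two adjacencies
  sA <- genome(1:4, signed = TRUE)
  sB <- genome(c(1, -2, 3, 4))
  expect_identical(breakpoint_distance(sA, sB), 2L)
  expect_error(breakpoint_distance(A, genome(1:5, signed = TRUE)), "signed")
  expect_error(breakpoint_distance(A, genome(1:6)), "gene count")
})

test_that("breakpoint distance is a bounded metric", {
  set.seed(11)
  for (trial in 1:100) {
    n <- sample(4:10, 1)
    sg <- trial %% 2 == 0
    A <- random_genome(n, sg); B <- random_genome(n, sg); C <- random_genome(n, sg)
    dAB <- breakpoint_distance(A, B)
    expect_identical(breakpoint_distance(A, A), 0L)
    expect_identical(dAB, breakpoint_distance(B, A))
    expect_lte(breakpoint_distance(A, C), dAB + breakpoint_distance(B, C))
    expect_gte(dAB, 0L)
    expect_lte(normalized_distance(A, B), 1)
    if (dAB == 0L) expect_true(genomes_equal(A, B))
  }
})

test_that("neighbourhood membership uses strict inequality", {
  A <- genome(1:5)
  B <- genome(c(1, 3, 2, 4, 5))  # d = 2, normalized 0.4
  expect_true(in_neighborhood(A, A, 0.01))
  expect_false(in_neighborhood(A, B, 0.4))
  expect_true(in_neighborhood(A, B, 0.41))
  expect_error(in_neighborhood(A, B, 0), "positive")
})

test_that("genome text files round-trip", {
  gs <- list(plain = genome(c(3, 1, 2, 5, 4)),
             turned = genome(c(-1, 4, -3, 2)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_genomes(gs, path)
  back <- read_genomes(path)
  expect_named(back, c("plain", "turned"))
  expect_true(genomes_equal(back$plain, gs$plain))
  expect_true(genomes_equal(back$turned, gs$turned))
  expect_false(is_signed(back$plain))
  expect_true(is_signed(back$turned))
  # comma-separated and commented input parses too
  writeLines(c("# comment", ">x", "2, 3, 1"), path)
  expect_true(genomes_equal(read_genomes(path)$x, genome(1:3)))
})
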