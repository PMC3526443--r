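#' Circular genome objects
#'
#' A `genome` represents a single circular chromosome as a cyclic order of
#' `n` distinct genes labelled `1..n`, optionally with an orientation
#' (sign) per gene. Two representations describe the same circular genome
#' when they are related by rotation, or by reflection (reading the circle
#' in the opposite direction); in the signed case a reflection additionally
#' flips every orientation. Equality is always decided on the canonical
#' form, see [canonical_form()].
#'
#' @param order integer vector: the gene order read around the circle.
#'   Negative entries are shorthand for reversed orientation and imply a
#'   signed genome.
#' @param signs optional vector of +1/-1 orientations, one per gene in
#'   `order`. Supplying `signs` makes the genome signed.
#' @param signed logical; force a signed genome even when all orientations
#'   are positive.
#' @return An object of class `genome` with fields `order` (integer
#'   permutation of `1..n`), `signs` (+1/-1 per position, or `NULL` when
#'   unsigned), and `n`.
#' @examples
#' genome(c(3, 4, 5, 1, 2))            # unsigned circular genome
#' genome(c(-1, -3, -2))               # signed, via negative labels
#' genome(1:4, signs = c(1, -1, 1, 1)) # signed, explicit orientations
#' @export
genome <- function(order, signs = NULL, signed = NULL) {
  if (!is.numeric(order) || length(order) == 0L)
    stop("`order` must be a non-empty numeric vector of gene labels")
  ord <- as.integer(order)
  if (any(ord == 0L)) stop("gene labels must be non-zero")
  if (any(ord < 0L)) {
    if (!is.null(signs)) stop("give orientations either as negative labels or via `signs`, not both")
    signs <- ifelse(ord < 0L, -1L, 1L)
    ord <- abs(ord)
  }
  if (!is.null(signs)) {
    signs <- as.integer(sign(signs))
    if (length(signs) != length(ord) || any(signs == 0L))
      stop("`signs` must give a +1/-1 orientation for every gene")
  }
  if (isTRUE(signed) && is.null(signs)) signs <- rep(1L, length(ord))
  if (identical(signed, FALSE) && !is.null(signs))
    stop("`signed = FALSE` contradicts supplied orientations")
  g <- structure(list(order = ord, signs = signs, n = length(ord)),
                 class = "genome")
  validate_genome(g)
  g
}

validate_genome <- function(g) {
  n <- g$n
  if (n < 3L)
    stop("circular genomes need at least 3 genes; n = ", n, " is degenerate")
  if (!identical(sort(g$order), seq_len(n)))
    stop("`order` must be a permutation of 1..n (duplicate or out-of-range labels)")
  if (!is.null(g$signs) && length(g$signs) != n)
    stop("`signs` length must equal the number of genes")
  invisible(g)
}

#' @export
print.genome <- function(x, ...) {
  lab <- if (is_signed(x)) paste0(ifelse(x$signs > 0, "+", "-"), x$order) else x$order
  cat(sprintf("circular %s genome, n = %d\n( %s )\n",
              if (is_signed(x)) "signed" else "unsigned", x$n,
              paste(lab, collapse = " ")))
  invisible(x)
}

#' @rdname genome
#' @param x object to test.
#' @export
is_genome <- function(x) inherits(x, "genome")

#' @rdname genome
#' @param g a `genome`.
#' @export
is_signed <- function(g) !is.null(g$signs)

# strict lexicographic a < b for equal-length integer vectors
lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0L)
  length(i) > 0L && d[i[1L]] < 0L
}

rotate_to_gene1 <- function(ord, signs) {
  i <- which(ord == 1L)
  idx <- c(i:length(ord), seq_len(i - 1L))
  list(order = ord[idx], signs = if (is.null(signs)) NULL else signs[idx])
}

#' Canonical linear representation of a circular genome
#'
#' Picks one fixed representative of the rotation/reflection equivalence
#' class: among the two gene-1-first readings of the circle (forward, and
#' reflected -- reversed order with all signs flipped in the signed case)
#' the lexicographically smaller one is returned, comparing gene order
#' first and orientations second (+ before -). The result is deterministic,
#' idempotent and identical for every representation of the same circular
#' genome, which makes genomes hashable and de-duplicable.
#'
#' @param g a `genome`.
#' @return A `genome` in canonical form.
#' @examples
#' canonical_form(genome(c(3, 4, 5, 1, 2)))  # -> (1 2 3 4 5)
#' canonical_form(genome(c(1, 5, 4, 3, 2)))  # reflection -> (1 2 3 4 5)
#' @export
canonical_form <- function(g) {
  stopifnot(is_genome(g))
  fwd <- rotate_to_gene1(g$order, g$signs)
  if (is.null(g$signs)) {
    bwd <- rotate_to_gene1(rev(g$order), NULL)
    pick <- if (lex_less(bwd$order, fwd$order)) bwd else fwd
    out <- structure(list(order = pick$order, signs = NULL, n = g$n),
                     class = "genome")
  } else {
    bwd <- rotate_to_gene1(rev(g$order), -rev(g$signs))
    # order decides first; tied orders fall back to signs with + < -
    key <- function(r) c(r$order, ifelse(r$signs > 0L, 0L, 1L))
    pick <- if (lex_less(key(bwd), key(fwd))) bwd else fwd
    out <- structure(list(order = pick$order, signs = pick$signs, n = g$n),
                     class = "genome")
  }
  out
}

#' Test two genomes for circular equality
#'
#' @param a,b genomes of the same signedness.
#' @return `TRUE` iff the canonical forms coincide.
#' @export
genomes_equal <- function(a, b) {
  if (is_signed(a) != is_signed(b) || a$n != b$n) return(FALSE)
  ca <- canonical_form(a); cb <- canonical_form(b)
  identical(ca$order, cb$order) && identical(ca$signs, cb$signs)
}

# a compact string key for hashing/de-duplication
genome_key <- function(g) {
  cg <- canonical_form(g)
  if (is.null(cg$signs)) paste(cg$order, collapse = ",")
  else paste(cg$order * cg$signs, collapse = ",")
}

#' Adjacency set of a circular genome
#'
#' The `n` unordered neighbour pairs read around the circle. For unsigned
#' genomes these are gene pairs; a gene of an `n`-gene genome occurs in
#' exactly two of them. For signed genomes each gene `g` contributes two
#' extremities, tail `t(g)` and head `h(g)`, and a positively oriented gene
#' is traversed tail to head; the adjacency between consecutive genes joins
#' the trailing extremity of the first to the leading extremity of the
#' second, so the pair for `+g +h` is `(h(g), t(h))` and reading the circle
#' backwards with flipped signs yields the same unordered pair. Every
#' extremity occurs in exactly one pair. Extremities are numbered
#' `t(g) = 2g - 1`, `h(g) = 2g`.
#'
#' @param g a `genome`.
#' @return An object of class `adjacency_set`: list with `pairs` (n x 2
#'   integer matrix, each row sorted), `codes` (unique integer encoding of
#'   each pair, ascending), `n`, and `signed`.
#' @examples
#' adjacencies(genome(1:5))
#' adjacencies(genome(c(1, -2, 3)))
#' @export
adjacencies <- function(g) {
  stopifnot(is_genome(g))
  n <- g$n
  nxt <- c(2:n, 1L)
  if (is.null(g$signs)) {
    a <- g$order; b <- g$order[nxt]
    lo <- pmin(a, b); hi <- pmax(a, b)
    codes <- (lo - 1L) * n + hi
  } else {
    a <- g$order; b <- g$order[nxt]
    sa <- g$signs; sb <- g$signs[nxt]
    x <- 2L * a - (sa < 0L)        # trailing extremity: head if +, tail if -
    y <- 2L * b - 1L + (sb < 0L)   # leading extremity: tail if +, head if -
    lo <- pmin(x, y); hi <- pmax(x, y)
    codes <- (lo - 1L) * (2L * n) + hi
  }
  o <- order(codes)
  structure(list(pairs = cbind(lo, hi, deparse.level = 0)[o, , drop = FALSE],
                 codes = codes[o], n = n, signed = is_signed(g)),
            class = "adjacency_set")
}

#' @export
print.adjacency_set <- function(x, ...) {
  cat(sprintf("adjacency set: %d pairs (%s genome, n = %d)\n",
              nrow(x$pairs), if (x$signed) "signed" else "unsigned", x$n))
  invisible(x)
}

check_comparable <- function(a, b) {
  if (!is_genome(a) || !is_genome(b)) stop("both arguments must be genomes")
  if (a$n != b$n) stop("genomes have different gene counts: ", a$n, " vs ", b$n)
  if (is_signed(a) != is_signed(b)) stop("cannot compare a signed with an unsigned genome")
  invisible(TRUE)
}

#' Number of shared adjacencies between two genomes
#'
#' @param a,b genomes on the same gene set and signedness.
#' @return Integer count `adj(a, b)` in `0..n`.
#' @export
shared_adjacencies <- function(a, b) {
  check_comparable(a, b)
  sum(adjacencies(a)$codes %in% adjacencies(b)$codes)
}

#' Breakpoint distance between circular genomes
#'
#' `d(A, B) = n - adj(A, B)` where `adj(A, B)` counts adjacencies common to
#' both genomes: a pair of genes (gene extremities, in the signed case)
#' consecutive in one genome but not the other is a breakpoint. The
#' distance is an exact integer in `0..n`; [normalized_distance()] divides
#' by `n` only at reporting time, so no float drift enters comparisons.
#'
#' @param a,b genomes on the same gene set and signedness.
#' @return Integer breakpoint distance.
#' @examples
#' breakpoint_distance(genome(1:5), genome(c(1, 3, 2, 4, 5)))  # 2
#' @export
breakpoint_distance <- function(a, b) {
  check_comparable(a, b)
  a$n - sum(adjacencies(a)$codes %in% adjacencies(b)$codes)
}

#' @rdname breakpoint_distance
#' @return `normalized_distance()`: `d(a, b) / n`, a value in `[0, 1]` --
#'   two genomes of length `n` can disagree on at most `n` adjacencies.
#' @export
normalized_distance <- function(a, b) breakpoint_distance(a, b) / a$n

#' Normalized-distance neighbourhood test
#'
#' `b` lies in the epsilon-neighbourhood of `a` when
#' `d(a, b) / n < eps` (strict inequality).
#'
#' @param a,b genomes on the same gene set and signedness.
#' @param eps neighbourhood radius as a fraction of `n`; must be positive.
#' @return Logical.
#' @export
in_neighborhood <- function(a, b, eps) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0)
    stop("`eps` must be a single positive number")
  normalized_distance(a, b) < eps
}

#' Read and write circular genomes as plain text
#'
#' One genome per record: an optional `>name` header line followed by one
#' line of whitespace- or comma-separated integer gene labels; a leading
#' `-` marks reversed orientation in signed genomes. Records are implicitly
#' circular. Blank lines and `#` comment lines are ignored.
#'
#' @param path file path.
#' @return `read_genomes()`: a named list of `genome` objects.
#' @export
read_genomes <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(); nm <- character(0)
  pending <- NA_character_
  for (ln in lines) {
    if (startsWith(ln, ">")) {
      pending <- trimws(sub("^>", "", ln))
      next
    }
    vals <- as.integer(strsplit(ln, "[,[:space:]]+")[[1L]])
    if (anyNA(vals)) stop("could not parse genome record: ", ln)
    out[[length(out) + 1L]] <- genome(vals)
    nm <- c(nm, if (is.na(pending)) paste0("genome_", length(out)) else pending)
    pending <- NA_character_
  }
  names(out) <- nm
  out
}

#' @rdname read_genomes
#' @param genomes a `genome` or list of genomes.
#' @param names optional record names; defaults to list names.
#' @return `write_genomes()`: the path, invisibly.
#' @export
write_genomes <- function(genomes, path, names = NULL) {
  if (is_genome(genomes)) genomes <- list(genomes)
  if (is.null(names)) names <- names(genomes)
  if (is.null(names)) names <- paste0("genome_", seq_along(genomes))
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    stopifnot(is_genome(g))
    lab <- if (is_signed(g)) g$order * g$signs else g$order
    writeLines(c(paste0(">", names[i]), paste(lab, collapse = " ")), con)
  }
  invisible(path)
}
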