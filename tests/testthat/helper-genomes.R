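# shared fixtures: random genomes/instances and an independent orbit
# enumerator used to validate canonicalization

random_genome <- function(n, signed = FALSE) {
  ord <- sample.int(n)
  if (signed) genome(ord, signs = sample(c(1L, -1L), n, replace = TRUE))
  else genome(ord)
}

random_instance <- function(n, k = 3, signed = FALSE) {
  median_instance(replicate(k, random_genome(n, signed), simplify = FALSE))
}

# every linear representation of the circular equivalence class of g:
# n rotations, and n rotations of the reflection (reversed order, signs
# negated when signed) -- independent of the package's canonicalization
orbit_representations <- function(g) {
  n <- g$n
  rot <- function(ord, sg, i) {
    idx <- c(i:n, seq_len(i - 1L))
    list(order = ord[idx], signs = if (is.null(sg)) NULL else sg[idx])
  }
  refl_ord <- rev(g$order)
  refl_sg <- if (is.null(g$signs)) NULL else -rev(g$signs)
  out <- list()
  for (i in seq_len(n)) {
    out[[length(out) + 1L]] <- rot(g$order, g$signs, i)
    out[[length(out) + 1L]] <- rot(refl_ord, refl_sg, i)
  }
  lapply(out, function(r) genome(r$order, signs = r$signs))
}

genome_label <- function(g) {
  cg <- canonical_form(g)
  if (is.null(cg$signs)) paste(cg$order, collapse = ",")
  else paste(cg$order * cg$signs, collapse = ",")
}
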