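---
title: "Breakpoint medians of circular genomes: model, solver, and simulation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Breakpoint medians of circular genomes: model, solver, and simulation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpmedian)
```

## The model

A genome here is a single circular chromosome over genes `1..n`, n ≥ 3
(smaller circles have no well-defined distinct adjacencies and are
rejected). Two linear writings describe the same genome when they differ by
rotation or reflection; in the signed case, where each gene carries an
orientation, a reflection also flips every orientation. `canonical_form()`
fixes one representative per class — the lexicographically smaller of the
two gene-1-first readings — so equality, hashing and solution
de-duplication are deterministic.

The *adjacency set* of a genome is its n unordered neighbour pairs. For
signed genomes each gene `g` contributes a tail `t(g) = 2g − 1` and head
`h(g) = 2g`; a positively oriented gene is traversed tail→head and an
adjacency joins the trailing extremity of one gene to the leading extremity
of the next, which makes the adjacency of `+g +h` and that of `−h −g` the
same unordered pair by construction. The breakpoint distance is
`d(A, B) = n − adj(A, B)` with `adj` the shared-adjacency count; distances
are exact integers throughout and are normalized by n only at reporting
time, so no floating-point drift can enter a comparison. The normalized
distance is at most 1, and for two independent uniform random genomes the
shared-adjacency count is asymptotically Poisson — rate 2 unsigned (a given
adjacency of A appears in a random B with probability ≈ 2/(n−1)), rate 1/2
signed (the orientations must also agree) — so the expected normalized
distance tends to 1 in both spaces. The test suite checks the rates at
n = 1000 over 2000 pairs.

Given k ≥ 3 genomes, a *median* minimizes the median sum Σᵢ d(M, Aᵢ). The
TSP reduction builds the complete graph on the n genes (2n extremities when
signed) with weights `w(xy) = k − v(xy)`, `v` counting the inputs containing
adjacency xy. Every Hamiltonian tour decodes to a genome whose median sum
equals the tour weight exactly — an integer identity the suite verifies on
thousands of random tours — so a minimum-weight tour is a median. In the
signed case the n intra-gene (tail, head) edges are *structurally forced*
into every tour (a hard constraint, not a large negative weight, which
avoids any weight-scale pathology), so tours alternate gene traversals and
adjacencies and orientations are read off the traversal direction.

## The exact solver

No general integer-programming machinery is assumed: the solver is a
depth-first branch and bound specialized to these graphs.

* **Bounds.** Held–Karp 1-tree Lagrangian bounds: a minimum spanning tree
  over all vertices but one, plus that vertex's two cheapest edges, with
  vertex penalties updated by subgradient ascent (about 5N iterations at
  the root, 50 in children, penalties warm-started down the tree).
* **Integrality.** Edge weights are integers in `0..k`. The incumbent's
  integer cost prunes any node whose bound exceeds `best − 1 + 0.05`: a
  node can only matter if it contains a tour at least one whole unit
  better.
* **Tie-breaking and optimum sampling.** Before each solve the genes are
  randomly relabeled and every edge weight receives a seed-derived random
  perturbation, scaled so that a full tour accumulates less than 0.05 —
  far below the integer resolution, so certified optimality always refers
  to the exact integer instance. The perturbation decides which of many
  co-optimal tours the spanning trees, the 2-opt/Or-opt local search and
  the incumbent tie-breaks reach first; equal-integer-cost incumbents are
  kept by perturbed cost, and the input tours are processed in random
  order. Varying the seed in `sample_medians()` therefore samples
  alternative optima, in the same spirit as re-seeding an external TSP
  code. Whether such seed-variation samples the optimum set *uniformly* is
  not known (the same caveat applies to re-seeding any black-box solver);
  what the suite checks instead is the observable consequence: corner
  solutions accumulate exchangeably across the inputs (chi-square,
  α = 0.01), and on tiny instances the sampler reaches multiple members of
  the exhaustively enumerated optimum set.
* **Certification and failure.** `mode = "exact"` returns only
  bound-certified optima and raises an explicit error when the node or
  time budget is exhausted — never a silent fallback. `mode = "heuristic"`
  (nearest-neighbour plus 2-opt/Or-opt over the best input tour) reports
  the root Lagrangian bound rounded up to an integer lower bound and sets
  `certified` only when it meets the tour cost. Saturated random unsigned
  instances at n = 100 close at the root node in milliseconds; exact use
  beyond n ≈ 150 is not the design point.
* **Oracles.** Two independent implementations guard the solver:
  exhaustive enumeration of all circular classes (n ≤ 8 unsigned, n ≤ 5
  signed) and a bitmask Held–Karp dynamic program (unsigned, n ≤ 13). The
  acceptance suite replays solver-versus-oracle equality on 70 random
  instances.

## The synthetic genomes

The generators produce exactly the study's inputs, and nothing more
biological than that:

* `identity_genome(n)` — the common starting point `1, 2, …, n`.
* `swap_randomize(g, s)` — s successive exchanges of two uniformly chosen
  gene positions; each swap creates at most four new breakpoints (so
  `d ≤ 4s`), and in the signed case each swapped gene's orientation is
  re-drawn uniformly — a swap may restore a sign, which keeps the kernel
  memoryless. Swap counts are absolute internally; drivers express them per
  100 genes (`round(s·n/100)`) so trajectories are comparable across n.
* `uniform_random_genome(n)` — a uniform linear permutation read
  circularly; all circular classes have equal-sized linear fibers, so the
  classes are sampled uniformly (verified by chi-square over the 12
  classes at n = 5). Signed draws add independent uniform orientations.
  (Counting signed genomes as 2ⁿ(n−1)! ignores the reflection quotient;
  since reflection fibers are also equal-sized, uniformity over classes is
  unaffected.)

Position swaps are a generic scrambling device chosen for neutrality; they
are **not** a model of inversions, transpositions or double-cut-and-join,
and none of the package's conclusions should be read as statements about
any particular rearrangement mechanism. What saturation under swaps shares
with any such model is only the endpoint: mutual randomization of the
inputs.

## Simulation design and defaults

`randomization_trajectory()` scrambles k inputs from the identity at each
level of a swap grid (default 0–300 per 100 genes in steps of 25), samples
`m_solutions` optima per instance, and records the normalized median sum,
the mean pairwise distance among sampled optima, and the corner/middle
census. All sub-seeds are drawn up front from the master seed in a
documented order (per level, per replicate: one seed per genome, then one
solver seed), so every record is replayable in isolation and different k
or n share no randomness. Solver failures produce `valid = FALSE` records
rather than disappearing.

Defaults are desk-scale: n = 60–100, 5 replicates per level, m = 10. The
saturation window used for asymptote estimates is 150–300 swaps per 100
genes — the saturation knee sits around 50–60, so 150+ is comfortably flat.
The package's own acceptance computations use n = 100 with 5 replicates at
each of four saturated levels for the trajectory asymptotes, n = 1000 with
2000 pairs for the adjacency statistics, and n ∈ {20, 40, 60, 80, 100} with
25 replicates of m = 20 for the corner-drift census; these sizes keep every
solve certified-exact. Much larger genomes are reachable in heuristic mode,
whose uncertified results are flagged and excluded from acceptance
statistics.

`classify_median()` calls a solution MIDDLE when its normalized distance
spread `(maxᵢ d − minᵢ d)/n` is at most `tau`, else CORNER of the nearest
input (smallest index on ties, for determinism). The default `tau = 0.05`
separates the two regimes observed for scrambled inputs — corner solutions
have spreads near 1, middle solutions near 0 — by a wide margin on both
sides; `eps = 0.1` is only a reporting radius for the `near_input` flag.
When all inputs coincide every distance is 0, the spread rule fires, and
the classification is pinned as MIDDLE by a unit test; this degenerate
verdict is a convention, not a finding.

## What the simulations do and do not show

The trajectories and censuses concern *random* genomes. They demonstrate
that the saturated normalized median sum approaches k − 1, that alternative
optima of one instance lie nearly (k − 1)/k apart because they drift to
different corners, and that the compromise ("middle") minority thins as n
grows while corner medians tighten onto their inputs. They do not quantify
how these biases enter real, phylogenetically structured gene orders —
real genomes are not uniform permutations, and moderate (pre-saturation)
rearrangement levels are exactly where the corner bias is partial and
hardest to summarize.

Two desk-scale caveats deserve emphasis. First, with m = 20 samples and
n ≤ 100 the middle fraction is small (a few per cent) and its decreasing
trend is weak relative to sampling noise; the census driver therefore
defaults to many replicates, and the nearest-input distance — whose
decline is much stronger at these sizes — is the more reliable trend
indicator. Second, the spread threshold spans `tau·n` discrete breakpoint
bins, so the middle count is coarser at small n; `tau` is configurable for
sensitivity analyses.

## Limitations

Single circular chromosomes with equal gene content only: no linear or
multichromosomal genomes, no duplications or losses. Breakpoint distance
only: medians under reversal or double-cut-and-join distances are out of
scope, as is any phylogenetic tree inference on top of medians. Exact
solving is designed for n up to roughly 150; the TSPLIB exporter
(`write_tsplib()`, explicit full matrix plus fixed edges) is provided for
anyone wishing to drive a heavyweight external solver at larger n.
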