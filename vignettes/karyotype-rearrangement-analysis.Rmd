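---
title: "Karyotype morphometrics and rearrangement parsimony with karyevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Karyotype morphometrics and rearrangement parsimony with karyevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Comparative cytogenetics of non-model animals — here, pulmonate land
snails of the genus *Trochoidea* — typically rests on morphometric
karyotype tables: for each homologous chromosome pair, the relative
length (R.L., the pair's length as a percentage of the total haploid
complement length) and the centromeric index (C.I., short-arm length as
a percentage of chromosome length, hence 0–50), each reported as mean ±
SD over a handful of measured metaphase plates. From such tables one
wants to

1. classify each pair into the conventional Levan shape classes —
   metacentric (M), submetacentric (sM), subtelocentric (sT),
   telocentric (T) — and summarize a karyotype as a *chromosomal
   formula* such as `19M, 4sM, 1sT`;
2. decide which pair in one karyotype corresponds to which pair in
   another, honouring measurement uncertainty;
3. reconstruct ancestral karyotypes on a phylogeny and count the
   minimal set of rearrangements — pericentric inversions (or
   centromeric shifts, observationally identical) and chromosome-number
   reducing translocations/fusions — that explains the extant
   karyotypes;
4. corroborate the comparison with a mitochondrial marker:
   uncorrected p-distances, a neighbour-joining tree, bootstrap
   support.

`karyevol` implements this pipeline end to end, with a synthetic-data
module that simulates every input it consumes.

```{r, eval = FALSE}
library(karyevol)
path <- system.file("extdata", "trochoidea_caroni_karyotypes.tsv",
                    package = "karyevol")
ks <- read_karyotype_table(path)
format(summarize_formula(classify_karyotype(ks$Capri)$pairs$shape))
#> [1] "19M, 4sM, 1sT"
```

## Shape classification

The Levan system is defined on arm ratios; expressed on the centromeric
index scale it reduces to four bands with cut points at 12.5, 25 and
37.5 (sM/M at arm ratio 1.7 is not representable exactly with these
printed conventions; the quarter-scale bands are the reduction used in
practice by the karyotype tables this package targets). Boundaries are
closed toward the metacentric side: C.I. = 37.5 is M. These defaults
reproduce all 24 published shape calls for the Capri population of
*Trochoidea caroni* and 23/24 for Palermo.

The one Palermo disagreement (pair 21, C.I. 35.8, printed M but inside
the sM band) is deliberately *not* silently resolved:
`classify_karyotype()` never overwrites a given label and instead
returns disagreements in a `label_conflicts` attribute. Published
labels may encode information beyond the printed mean (the authors saw
the plates; the mean may be dragged by one outlier measurement), so
both readings are kept and the conflict is surfaced as a data-quality
finding.

## Homology matching under measurement uncertainty

Two karyotypes of equal pair count are homologized by a minimum-cost
perfect matching (`pair_karyotypes()`). The cost of pairing `p` with
`q` is the squared z-distance

$$c(p, q) = \frac{(rl_p - rl_q)^2}{s_{rl,p}^2 + s_{rl,q}^2}
          + \frac{(ci_p - ci_q)^2}{s_{ci,p}^2 + s_{ci,q}^2},$$

i.e. the measurement SDs pooled in quadrature set the natural scale, so
the cost is unitless and comparable across pairs of very different
size. A matching may only move a pair to a *nearby rank*: position `i`
may map to `j` only if `|rl_i - rl_j| <= window_k (s_{rl,i} +
s_{rl,j})`, with `window_k = 2` by default ("within about two SDs").
`shape_penalty` (default 1) adds a unit cost when the matched pairs
carry different shape labels, a soft parsimony preference for matchings
that imply fewer rearrangements; setting it to 0 decouples matching
from shapes. SDs below `sd_floor = 0.1` percentage points are floored
so degenerate noise-free simulated inputs cannot yield infinite
z-scores.

Numerical determinism. The solver is an $O(n^3)$ Hungarian algorithm
with dual potentials. Ties among cost-optimal matchings are resolved
*exactly*, not by epsilon perturbation: every optimal matching is a
perfect matching of the dual-tight edge subgraph, on which the package
minimizes the number of displaced positions and then picks the
lexicographically least permutation, via integer assignment
subproblems. Fixed inputs therefore always give the same map.

## Scenario inference

`infer_scenario()` reconstructs ancestral states and per-edge events on
a rooted tree:

* **Alignment of leaves.** By default (`align = "index"`), pair rank
  order is taken as the homology statement. For conspecific population
  tables the shared numbering *is* the homology claim, and this default
  is what reproduces the published two-inversion difference between the
  Capri and Palermo populations. `align = "match"` instead re-matches
  every leaf to the first tip with `pair_karyotypes()`; this is the
  right mode across species ranked independently, but note its hazard:
  because the centromeric index enters the cost, a sufficiently cheap
  re-ranking can "explain away" a real inversion by pairing the
  rearranged chromosome with a similarly shaped neighbour. On the
  *T. caroni* table it does exactly that (one inferred inversion
  instead of two), which is why it is not the default.
* **Ancestral pair counts.** Fusions only reduce the count, so setting
  every internal node to the maximum of its children is the parsimony
  optimum; each drop along an edge contributes that many translocation
  events (diploid number −2 each). Fissions are not modeled.
* **Ancestral shapes.** Per position, unit-cost Sankoff dynamic
  programming (exact also for multifurcations) gives the minimal change
  count; the backtrace breaks ties toward the more metacentric class (M
  before sM before sT before T), anchored by the all-metacentric
  presumed primitive complement of the family. Each edge then carries
  one inversion per position whose labels differ. A change-cost matrix
  hook is exposed for later refinement; the default treats the four
  classes as an unordered alphabet because the literature counts
  events, not arm-ratio magnitudes.
* **Unequal pair counts.** Between two specific karyotypes,
  `infer_edge_events()` searches exhaustively over which parent pairs
  were lost to fusion (drops of at most 2, the deepest case in the
  genus; larger drops raise an error) and minimizes the residual
  inversion count. Inside a multi-leaf scenario, positions beyond a
  reduced leaf's count are compared by prefix alignment — a stated
  approximation: fusion-induced re-ranking can misattribute a shape
  change, so with fusions the inferred totals are a heuristic lower
  bound rather than an exact parsimony score. The quantitative recovery
  guarantees below are therefore stated for inversion-only histories.

## The sequence module

`p_distance()` is the uncorrected proportion of differing sites among
sites where both sequences have an unambiguous base (pairwise deletion
of gaps and N) — the statistic conventionally reported alongside these
karyotype studies; no substitution-model correction is applied, because
none is implied by that statistic. `nj_tree()` is a from-scratch
Saitou–Nei implementation: Q-criterion minimization with ties broken by
the smallest index pair, the usual branch-length formulas, negative
lengths clamped to zero with a warning, and a trifurcating basal node.
`bootstrap_support()` resamples columns with replacement, rebuilds the
NJ tree per replicate, and maps split frequencies (percent) onto the
full-data tree; it is deterministic per seed. The alignment step itself
(ClustalW-style) is out of scope — aligned input is consumed as given.

## What the generators emulate — and what they do not

`simulate_measurements()` mirrors how such tables arise: five replicate
Gaussian measurements per pair (five metaphase plates is the
conventional design), reported as mean ± SD, relative lengths
renormalized to sum to 100, centromeric indices clamped to [0, 50].
Defaults: `rl_sd = 0.5`, `ci_sd = 2.0` percentage points, the scale of
the published *T. caroni* table; the default true relative-length
profile is linear from 7.5% down to 1.9%, again the published span.

`simulate_karyotype_evolution()` starts from an all-metacentric root
(the presumed primitive state) and applies per edge
Poisson(`inversion_rate`) shape flips — position uniform, target class
uniform among the other three, centromeric index redrawn inside the
target band — and Poisson(`translocation_rate`) fusions, each appending
the lost pair's length to a survivor's long arm (so the survivor's
index shrinks, typically toward submetacentric, which is the documented
signature of such fusions). Every event is recorded as ground truth.
The default `inversion_rate = 0.25` per edge keeps histories in the
sparse regime (about 1.5 expected events on a 6-edge tree), the scale
of the published two-population comparison. This matters for
interpreting green tests: parsimony is a lower bound, and at rates near
0.5/edge multiple hits at one position (same-edge double flips,
parallel sibling changes, reversals) already make ~8% of histories
non-minimal — no inference method can recover those totals from the
leaves. A green recovery test therefore establishes that inference is
exact *when the true history is parsimonious*, not that the rate
parameter is irrelevant.

What is deliberately not emulated: correlated measurement error between
the five plates (real plates share preparation artifacts), karyotype
measurement heteroscedasticity beyond the configured scales,
heterochromatin gain/loss (dismissed as improbable for these taxa),
fission events, and any NOR/FISH signal — the NOR-bearing pair is
carried as an annotation only.

`simulate_alignment_jc()` evolves sequences by the exact Jukes–Cantor
per-edge transition probability $p = \tfrac34(1 - e^{-4d/3})$, so
two-leaf p-distances match the closed form in expectation and the
process composes correctly along paths.

## Numerical and design choices

* Relative-length sums are accepted within ±1.0 of 100 (published
  columns sum to 100.1 and 100.0 due to per-pair rounding).
* The Palermo pairs 21–24 print relative-length SDs of the same
  magnitude as the means — almost certainly transcription artifacts.
  They are stored as printed and flagged by a validation warning
  (`rl_sd > 0.5 * rl_mean`), never corrected.
* Scenario reports are byte-stable JSON (sorted node keys, sorted
  events, no timestamps), so identical analyses diff as identical
  files.
* All generators take a mandatory seed, restore the caller's RNG
  state, and are byte-identical on rerun.
* The matcher's brute-force validation uses exhaustive permutation
  enumeration up to n = 8 and an exact branch-and-bound oracle on the
  real 24-pair instance, where the feasible-permutation count is
  astronomically large.

## Known limitations

* Homology matching assumes equal pair counts; across different
  diploid numbers, correspondence is only resolved at the level of
  fusion counts plus the d ≤ 2 exhaustive position search.
* The six-inversion derivation published for *T. elegans* cannot be
  reproduced: the printed shape counts it implies are internally
  inconsistent with the stated ancestral formula, so the package makes
  no attempt to recover that particular claim.
* Bootstrap support is attached to the full-data topology;
  majority-rule consensus output is not implemented.
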