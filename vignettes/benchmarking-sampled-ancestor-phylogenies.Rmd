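---
title: "Benchmarking phylogenies against a known sampled-ancestor tree"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking phylogenies against a known sampled-ancestor tree}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylobench)
```

## The setting

A serial-passage experiment fixes a phylogeny by protocol: a founder
culture `S` is split into two daughters each day, every culture is sampled
daily, and after 8 days the 255 samples stand in a known ancestor–descendant
relationship — `S` is literally the ancestor of `S1` and `S2`, and so on.
About half of the sequenced samples are therefore *sampled ancestors*: they
belong at internal nodes of the true tree. Phylogenetic reconstruction
methods, by contrast, place every observed sequence at a leaf. The package
implements the post-processing and scoring machinery that reconciles the
two representations, plus a simulator so the whole pipeline can be
exercised without any external data.

## The labeled-tree container

All operations work on a `labeled_tree`: a rooted tree whose every node
carries an ordered set of zero or more sample names and a branch length to
its parent. This deliberately admits shapes that leaf-centric containers
reject — named internal nodes, anonymous nodes, single-child chains,
multi-name nodes, negative branch lengths (distance methods occasionally
produce them; they are stored as given, never clamped). Trees are treated
as rooted as written; no re-rooting is attempted, because both similarity
measures are defined on rooted trees.

Newick serialization encodes a multi-name node by joining its names with a
configurable delimiter (default `|`), chosen because a standard Newick
parser sees such a label as one plain string, so collapsed trees survive
round trips through third-party tools. The writer is deterministic
(children in stored order, 6 significant digits by default); the root never
carries a branch length.

## Collapsing short branches

`collapse_fixed(tree, cutoff)` contracts every branch with length
`<= cutoff`: the child's names merge onto the parent and the child's
children re-attach with their own lengths unchanged, applied to a fixpoint
so chains of short branches merge into one node (this is how nodes with
three or more names arise). Two deliberate choices:

* The comparison is `<=`, so a cutoff of 0 collapses zero-length **and**
  negative branches — the negative lengths a distance method emits are
  exactly the branches one wants gone.
* The root is never collapsed away, and its (meaningless) branch length is
  ignored.

`collapse_adaptive(tree, target_leaves)` chooses the cutoff from the data:
the distinct branch lengths of the input, ascending, are tried until at
most `target_leaves` leaves remain (the motivating benchmark had 101
sequences of which 50 were true leaves, so 50 was the target there). The
search re-collapses from the original tree at each candidate; by
idempotence and monotonicity this is equivalent to an incremental search,
and the test suite asserts that equivalence rather than assuming it. When
the input already meets the target, nothing is collapsed and the reported
cutoff is the sentinel `-Inf`. Collapsing conserves the name multiset, is
idempotent at a fixed cutoff, and leaf count is non-increasing in the
cutoff — all property-tested.

## The two similarity measures

A tree is scored against the known ("benchmark") tree on two derived
representations:

* **Parent–child relations**: for every branch from node *P* to child *C*,
  all ordered name pairs `(p, c)` with `p` at *P* and `c` at *C*. Anonymous
  ends contribute nothing. The score is the fraction of the *benchmark's*
  relations present in the investigated tree.
* **Labeled clades**: for every internal node, the set of all names
  strictly descendant from it — internal names included, which is what
  distinguishes this from leaf-set bipartition measures. The score is the
  fraction of benchmark clades found, with exact set equality and multiset
  semantics (duplicate identical clades each need a distinct match).

Design choices the definitions leave open, decided here:

* Both denominators are the benchmark's counts. The clade measure's
  definition forces that choice for clades; parent–child is made symmetric
  with it. Names missing from the investigated tree simply count as
  unrecovered (in the motivating 101-vs-101 comparison this cannot occur).
* Two names co-located on one collapsed node satisfy a true parent–child
  pair between them: co-location is the collapse representation of a
  zero-length true branch, and penalizing it would punish correct
  inferences. Co-location pairs are flagged separately by
  `parent_child_relations()` and never enter the benchmark's denominator.

## Resolutions of ancestral nodes

On a rooted bifurcating tree, an ancestral sequence can be placed as a leaf
next to its internal node in exactly 3 ways (sister to either child, or
outgroup to both); with two identical-sequence occupants there are 15, the
number of rooted bifurcating trees on 4 leaves. In general a node with
*m* occupants and *c* children admits `rooted_tree_count(m + c)` local
resolutions — the double factorial `(2n-3)!!` — independently across nodes,
so a fully sampled 8-day binary design tree has `3^127 ≈ 3.9e60` equally
good leaf-only resolutions. `resolve_random()` draws one uniformly (by
sequential uniform edge insertion, which is exact for this distribution),
`enumerate_resolutions()` generates all of them for small trees, and the
uniformity of the three single-occupant configurations is checked by a
chi-square test over 3000 seeds. The central invariant — collapsing any
resolution at cutoff 0 reconstructs the original tree exactly, with both
scores 1 — is the round-trip oracle the test suite leans on.

## The simulator

`simulate_experiment()` emulates the wet-lab experiment at the consensus
level: one genome per node, because a daily single-colony bottleneck means
the consensus of each day's population is the founding cell's genome (at
~5 mutations/day on a 4.6 Mb genome, only ~1 read in a million carries any
given new mutation, so read-level simulation would add nothing here).
Per branch (one day), `K ~ Poisson(mu)` substitutions hit distinct
positions; across days a site can be hit again, so homoplasy appears
naturally at a rate that vanishes as genome length grows. The spectrum is
mutT-like: with probability `at_to_gc_bias` a mutation picks an A or T
site and applies A→C / T→G (the strand-complementary pair of the mutT
lesion); otherwise any site changes to any other base.

Defaults are the study conditions: 8 days, binary splits, μ = 3.3
mutations/genome/day (the rate the diffs-to-root estimator observed in the
motivating experiment; the plate-assay expectation was ≈5.4), bias 0.9
(the biology says only "prone to AT→GC", so the exact value is a free
parameter; 0.9 makes the bias dominant without being degenerate), and
sequencing success 101/255 per sample, matching the experiment's yield.
The default 100 kb genome keeps desk-scale runs fast while holding
per-branch homoplasy below ~10⁻⁴ per mutation; 4.6e6 gives a realistically
sized *E. coli* genome. An optional `fixed_count` mode applies exactly
`round(mu)` mutations per branch — the observed per-day counts in such
experiments can be *underdispersed* relative to Poisson, and this mode
reproduces that signature (dispersion index < 1); it is not the default
because the default model is the plain Poisson clock.

What the simulator does **not** model: sequencing error, indels,
recombination, selection, within-population diversity. Tests that pass on
simulated data therefore certify the tree machinery and the estimator
arithmetic, not robustness to those real-data complications.

## Rate estimation

`estimate_rate_per_day()` counts, for each isolate, the positions differing
from the root isolate's sequence and divides by the isolate's age in days
(sampling day minus the root's day, derived from the design names when not
given explicitly; the root is excluded from the mean). Ambiguous positions
(non-ACGT) are skipped and the skip count reported. On simulated data the
estimator recovers μ within Monte-Carlo error — the parameter-recovery
test runs μ ∈ {1, 3.3, 5} over 20 replicate seeds each, 8 days, 100 kb
genomes, and requires agreement within 3 standard errors of the replicate
means. The homoplasy bias is downward and of order μ·days/genome_length,
negligible at these sizes.

`dispersion_vs_poisson()` reports variance/mean of the per-day values with
a histogram on unit-width bins centered on integers and the Poisson pmf at
the sample mean for overlay. Note that rates averaged over multi-day paths
are smoother than single-branch counts, so even a Poisson-clock simulation
yields an index well below 1 for the diffs-to-root rates; the index of
raw per-branch counts is ~1, and the fixed-count mode drives it toward 0.

`assay_fold_change()` normalizes mean colony counts by plated volume and
returns the mutator/wild-type ratio. With the documented example counts
({9, 6, 15, 5} vs {170, 240, 180, 148}, 800 vs 100 µL) the volume-normalized
fold is ≈169; published analyses of the same counts have quoted values in
the low 160s depending on the averaging scheme, which is why the function
computes the fold from its inputs rather than fixing a constant.
`expected_mutations_per_day(rate, minutes, fold)` is the closing
arithmetic: `fold × rate × 1440/minutes` (0.048/day for the wild type at
10⁻³ per generation and 30 min; ≈5.4/day for a 164-fold mutator at 44 min).

## Numerical and degenerate-input choices

* Branch lengths are compared to cutoffs exactly (no epsilon); exhaustive
  contraction makes tie handling automatic.
* `rooted_tree_count()` returns doubles — the counts overflow 32-bit
  integers at 13 leaves.
* Scores are undefined (an error, not NA) on a benchmark with no relation
  or no internal node: a single-node benchmark cannot anchor a comparison.
* `restrict_to_observed()` dissolves every unobserved non-root node,
  re-attaching children to the nearest kept ancestor with branch lengths
  summed, so each surviving branch spans the path between consecutive
  observed samples; an unobserved root survives anonymously only while it
  has ≥ 2 observed lineages (keeping clades well defined) and is contracted
  away otherwise.
* Random draws (`resolve_random`, `simulate_experiment`) take an optional
  seed, set and restore the R RNG state locally, and are byte-reproducible
  given it.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: design trees of 2–6 days for round-trip properties (100+ cases),
exhaustive resolution enumeration up to 27 trees, and rate recovery on
8-day, 100 kb-genome simulations with 20 replicate seeds per μ. These sizes
were chosen so the full suite exercises every code path at full statistical
strictness (3 SE bounds) while remaining a desk-scale computation.

## Known limitations

* The benchmark scores of real reconstruction pipelines cannot be
  reproduced here: they require the original sequencing reads and the
  external read-mapping/SNP pipelines, which are out of scope by design.
* The two measures are defined for rooted trees only; unrooted comparisons
  and branch-length-weighted variants are non-goals.
* `resolve_random()` requires occupied internal nodes to have exactly two
  children (the design-tree shape); occupied multifurcations raise an
  error rather than guessing a resolution space.
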