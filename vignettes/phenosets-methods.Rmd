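---
title: "Phenotype gene sets: models, statistics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotype gene sets: models, statistics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosets)
```

## The problem

Genetic perturbation screens and variant curation in *C. elegans* and
*D. melanogaster* yield large tables of gene–phenotype associations: one
row says that perturbing gene *g* produced phenotype *p*. Collapsed into
*phenotype gene sets* — each phenotype term with its unique annotated
genes — these tables become a gene-set collection describing distal,
organism-level outcomes (sterile, slow growth, long lived) rather than
molecular function. `phenosets` implements the derivation of such
collections, a genome-wide model of how phenotypes relate through shared
genes, parametric gene-set analysis of expression contrasts, and PCA of
the resulting gene-set Z values. This vignette records the methods, their
assumptions, the tunable parameters, and the choices made where the design
was genuinely open.

## Derivation of collections

`parse_association_table()` supports two dialects. `worm_pairs` expects
gene and phenotype columns, with genes possibly printed as
`locus_tag(symbol)`; `normalize_gene_label()` splits that form, keeping
the locus tag as the canonical identifier and the symbol as metadata only.
`fly_alleles` expects allele and phenotypic-descriptor columns; allele
symbols are reduced to genes by a pluggable `allele_to_gene` hook, by
default stripping a bracketed allele designation (`"arm[4]"` → `"arm"`),
because the mapping used to produce published fly descriptor lists is not
specified anywhere we can implement from. Each full descriptor stays its
own term — no ontology roll-up is attempted.

Three normalization rules matter downstream:

* **Gene identity is case-insensitive.** Curated dumps print the same gene
  as `HIS-48` and `his-48`; membership, overlap, and matching all compare
  upper-cased identifiers while storing the first-seen casing.
* **Symbols are metadata.** Only `gene_id` participates in membership and
  overlap, preventing a gene counted once under its tag and once under its
  symbol.
* **Phenotype terms are whitespace-normalized to underscores**, since the
  same term appears both as `life span variant` and `life_span_variant`.

`build_collection()` drops duplicate (phenotype, gene) combinations, so
the sum of set sizes equals the number of unique pairs — an invariant the
tests check against the generator's ledger. Malformed rows are skipped and
counted rather than fatal: large curated dumps routinely contain stray
rows, and aborting on them would make the parser useless in practice.

## The genome-wide phenotype model

The distance between two sets is one minus the overlap (Szymkiewicz–
Simpson) coefficient,
`d_ij = 1 − |C_i ∩ C_j| / min(N(C_i), N(C_j))`, which is 0 for identical
*or nested* sets and 1 for disjoint ones. Nestedness at distance zero is a
deliberate property of the min-denominator: a specific phenotype whose
genes all belong to a broader phenotype is phenotypically "inside" it.

`fit_tree()` fits an unrooted tree whose leaf-to-leaf path lengths
approximate these distances by minimizing

```
SS = sum_{i<j} n_ij * (D_ij - d_ij)^2 / D_ij^P
```

with `P = 2` (Fitch–Margoliash weighting; the default) or `P = 0`
(unweighted least squares), and `n_ij = 1` unless replicate counts are
supplied. Numerical choices:

* **Each unordered pair is summed once.** A full double sum over ordered
  pairs doubles the criterion without moving the minimizer; the pair-based
  form matches standard least-squares tree fitting.
* **Zero off-diagonal distances** (identical or nested sets) would give an
  infinite `1/D^P` weight; they are replaced by
  `zero_distance_epsilon = 1e-6` with a warning. In practice nested sets
  should usually be merged or filtered before modeling.
* **Branch lengths are constrained nonnegative** by default
  (clamp-to-zero with refit of the remaining branches), matching the usual
  convention for distance trees; `allow_negative_branches` lifts the
  constraint.
* **Topology search** is stepwise leaf addition in lexicographic label
  order — each candidate placement scored by a full weighted
  least-squares branch refit — followed by nearest-neighbor-interchange
  hill climbing; ties break on the lexicographically smallest canonical
  Newick string, so results are deterministic. An agglomerative
  neighbor-joining start (`start = "nj"`, via `ape::nj`) is provided as a
  faster seed for collections with hundreds of leaves, where stepwise
  addition's quadratic-per-leaf cost dominates. For six or fewer leaves
  the tests verify the search attains the exhaustive-enumeration optimum;
  beyond that, as for all heuristic tree searches, only local optimality
  is guaranteed.

Tests verify that additive matrices (generated forward from known trees)
are recovered with criterion 0 and exact fitted distances, that the
criterion matches a brute-force double-loop evaluation, and that planted
two-block collections yield a tree containing the block bipartition.

## Parametric gene-set analysis

Per-gene change scores may be plain log-ratios or **Z-ratios**: after
per-sample Z normalization (`zscore_normalize()`, sample SD with n − 1),
the per-gene difference of group means is divided by the SD of those
differences across genes, so the contrast is on a unit scale regardless of
platform. `run_gsa()` then computes, per set,

```
Z_i = sqrt(n_i) * diff_i / sigma_a,   diff_i = mean(GC_i) - mean(GC_a)
```

with `n_i` the number of set genes *matched to the scores* (the filter
bounds, default 3–500 inclusive, count matched genes, since the statistic
is defined on the measured subset), `sigma_a` the sample SD of all scores.
The scaling by `sqrt(n_i)` is the standard parametric (PAGE) form: under a
null in which a set is an arbitrary selection of `n_i` genes from the
score distribution, Z is approximately standard normal by the central
limit theorem. Some descriptions of the statistic typeset the multiplier
ambiguously as `n_i − 1`; a `statistic = "literal"` switch implements that
reading, but it is off by default because it has no distributional
justification.

The reported p-value is the normal-theory two-sided tail
`p = 2(1 − Φ(|diff_i| / σ(diff_i)))` with
`σ(diff_i) = sqrt(σ_i²/n_i + σ_a²/n_a)`, treating set and array means as
independent averages. Two calibration notes, both verified by simulation
in the tests:

* Because the set is in fact a subset of the array, this p is very
  slightly conservative; with `n_i` up to 50 against 2000 genes the
  realized type-I error at 0.05 sits near 0.045–0.06.
* The Monte-Carlo oracle the tests compare against draws random sets
  **iid from the empirical score distribution** (with replacement). That
  is the null the parametric reference models. Sampling without
  replacement instead carries a finite-population factor
  `sqrt(1 − n_i/n_a)` — at `n_i/n_a = 0.1` enough to shift mid-range
  p-values by ~0.03 — which the PAGE statistic deliberately ignores;
  users testing large sets against small score vectors should interpret
  borderline p-values accordingly.

Multiple testing uses Benjamini–Hochberg across the surviving sets of a
contrast (`stats::p.adjust`; the tests check it against an independently
coded step-up). The choice of BH is convention, not mandate; the q column
is plain BH output and can be recomputed under any other procedure.

## PCA of gene-set Z values

`project_samples()` centers each row (gene set) of the Z matrix, takes the
SVD, and reports sample coordinates `V·S` with variance fractions
`d_k²/Σd²`. Centering is the only preprocessing by default — the row
scale of a Z matrix is already comparable — with `scale_rows = TRUE`
available where sets with extreme variance should not dominate. SVD signs
are arbitrary, so each component's sign is fixed by making its
largest-magnitude loading positive; outputs are reproducible across runs
and platforms.

## The synthetic-data generator

The generator exists so that every stage has a test surface with known
ground truth; its ledger (block assignments, memberships, per-gene true
shifts) fully determines the outputs given the seed.

`simulate_association_table()` partitions phenotypes evenly into blocks
and splits the gene pool into disjoint per-block shared pools (half the
pool) plus background. Each gene of a set is drawn from its own block's
pool with probability `within_block_sharing` (default 0.8), another
block's pool with `between_block_sharing` (default 0.05), else the
background. The defaults (20 phenotypes, 150-gene pool, set sizes 8–15)
give block pools about three times the median set size, so within-block
pairs share several genes (mean distance ≈ 0.75–0.8) while between-block
pairs rarely share any (≈ 0.97) — the regime the real worm collections
occupy, where related phenotype pairs share a minority of genes. The two
probabilities must sum to at most one; they are draw probabilities of a
three-way mixture.

`simulate_expression()` adds iid normal noise (σ = 1) to zero baselines
and shifts a target set's genes by δ in the designated group's samples.
Default group sizes of 3–4 samples match small published aging
time-course designs. The generator emulates neither platform-specific
probe effects, nor correlated gene noise, nor missingness beyond dropout:
passing tests demonstrate correctness of the statistics under the stated
model, not robustness to array artifacts.

Simulation sizes used by the test suite and the acceptance script —
2000-gene score vectors, 2000 random null sets, 20 generator seeds for
tree and PCA recovery, 10⁵-draw resampling oracles — were chosen as the
smallest sizes at which the Monte-Carlo error is well below each
property's acceptance band.

## Degenerate inputs and edge conventions

* Empty gene sets are invalid everywhere; distances on them error.
* A contrast whose per-gene differences are all equal (e.g. duplicated
  groups) has zero Z-ratio spread and is rejected as degenerate rather
  than returning infinities.
* `σ(diff_i) = 0` in the p-value returns 1 when `diff_i = 0` and 0
  otherwise (continuity convention, logged).
* Sets with no genes matching a contrast are skipped with a logged count,
  not errors: expression platforms never cover a curated collection
  completely.

## Known limitations

* The fly allele→gene mapping is heuristic by default; driver constructs
  (e.g. GAL4 lines) survive as "genes" exactly as they do in the
  published descriptor lists, and callers needing a curated mapping must
  supply one.
* Tree topology search is heuristic beyond small leaf counts; no
  bootstrap support is computed, and trees are unrooted with no branch
  annotation.
* The normal-theory p assumes approximately independent gene scores;
  correlated expression within a set inflates significance, as for all
  parametric gene-set statistics of this family.
* Collections with many mutually nested sets produce many zero distances;
  the epsilon substitution keeps the fit defined but such collections are
  better filtered first.
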