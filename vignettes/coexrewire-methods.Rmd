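---
title: "Differential coexpression, pathway rewiring and crosstalk: models and design choices"
author: "coexrewire"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential coexpression, pathway rewiring and crosstalk: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexrewire)
```

## The analysis in one paragraph

Many disease transitions alter not the expression *level* of genes but the
*coordination* between them: pairs of genes that track each other tightly in
a baseline state decouple as the disease advances. `coexrewire` quantifies
this at three scales. At the **gene-pair** level it calls differentially
coexpressed links (DCLs) — pairs whose Pearson correlation differs markedly
between two conditions — and differentially coexpressed genes (DCGs), genes
carrying significantly many DCLs. At the **pathway** level it tests whether
a gene set's internal correlation structure is rewired, extracts each
condition's hub gene, and classifies pathways as dissolved, consolidated or
maintained. At the **pathway-pair** level it asks whether the links that
*lost* correlation concentrate between two pathways — disrupted crosstalk.
A Fisher combined-probability layer aggregates pathway evidence across
several datasets, and permutation nulls calibrate how rare the observed hub
constancy and retention rates are.

## Gene-pair level: links, the LFC envelope, DCGs

All correlations are Pearson, computed separately in the two conditions over
the genes covered by the pathway compendium. A pair enters the **link
universe** if its absolute correlation reaches the top `density` fraction
(default 0.1) of all pairs in *either* condition; per-condition cutoffs are
the k-th largest |r| with k = ceiling(density × n pairs), ties included, so
the realized density is never below the target.

DCL calling distinguishes two situations:

* **Sign switches.** Pairs whose correlations have opposite signs in the two
  conditions (zero counts as positive) and exceed *both* per-condition
  cutoffs are DCLs outright (`diff_signed`).
* **Same-signed pairs** are scored by x = max(|r1|, |r2|) and
  fold = x / max(min(|r1|, |r2|), 1e-4). Pairs are stratified into B
  equal-count bins by x (B = 20, shrunk to ceiling(n/50) for small inputs);
  within each bin the top `dcl_fraction` (default 0.1) by fold is
  provisionally selected (ties broken by lexicographic pair order), the
  per-bin cutoffs (smallest provisional fold against the bin's median x) are
  smoothed by a least-squares power law y = a·x^b on the log scale, and a
  pair is a DCL when its fold reaches the envelope at its x. With a single
  bin the envelope degenerates to the bin's top-fraction boundary, which is
  exactly a top-k rule — this is the case the test suite checks against a
  brute-force oracle.

The ε = 1e-4 guard bounds folds when a correlation is essentially zero; the
bin-median x anchors the fit to a robust location per stratum. DCLs are
classified by sign and trend: `decreased_positive`, `increased_positive`,
`same_signed_negative`, `diff_signed`.

Each gene with k incident links and d incident DCLs gets a binomial tail
p = P(X ≥ d), X ~ Binomial(k, π), where π is the global DCL fraction among
links; Benjamini–Hochberg q < 0.1 flags DCGs. BH is used for all
multiple-testing adjustment in the package.

## Pathway level: eigenvector weights, permutation test, MST wiring

For a pathway with p ≥ 3 usable genes, the condition-specific **weight
vector** is the dominant eigenvector of the absolute correlation matrix with
zeroed diagonal, computed by power iteration (relative tolerance 1e-10, at
most 10 000 iterations), taken positive (Perron–Frobenius) and scaled to sum
to p. The rewiring statistic is the L1 distance between the two conditions'
weight vectors; significance comes from permuting condition labels over the
pooled samples (group sizes preserved) with the add-one estimator
p = (1 + #{d_perm ≥ d_obs}) / (1 + n_perm), n_perm = 1000 by default.
Permutations are seeded from the analysis seed plus a stable hash of the
pathway name, so per-pathway results are reproducible regardless of the
order in which pathways are processed. Genes with zero variance in either
condition are dropped per pathway, not imputed; a pathway reduced below 3
usable genes is skipped and enters meta-analysis conservatively as p = 1.

The **hub** is the maximum-weight gene (ties to the lexicographically
smallest name). The **wiring network** is the union of the first and second
minimum spanning trees of the complete graph under distances 1 − |r|,
computed by Kruskal's algorithm with the deterministic tie-break
(distance, gene_a, gene_b). One subtlety: for p ≥ 4 the residual graph
(complete minus the first tree) can still be disconnected — when the first
MST is a star, all edges at its center are gone — so the "second MST" is
computed as the minimum spanning *forest* of the residual. The union always
spans the pathway via the first tree and has exactly 2(p − 1) edges whenever
the residual is connected.

A pathway's **dissolution class** counts its internal DCLs whose correlation
moved down (|r2| < |r1|; sign switches count as decreased when
|r2| ≤ |r1|) versus up: `dissolved` when decreases predominate,
`consolidated` when increases do, `maintained` on an exact tie (a tolerance
parameter exists for near-ties but defaults to 0, the strict reading).

An important behavioural note: because eigenvector weights are
scale-invariant, a *uniform* attenuation of a correlation block (all |r|
shrinking by the same factor) leaves the weight vector unchanged in
expectation, and the test's power then comes only from the higher relative
noise of the weaker condition. With a planted hub (a gene whose correlation
advantage changes *relative* structure between conditions) the statistic
regains its intended sensitivity — the power study below therefore uses the
generator's default hub boost.

## Meta level: Fisher aggregation and focused pathways

Per-pathway p-values from k datasets combine as χ² = −2 Σ log p with 2k
degrees of freedom (upper tail). Zero p-values (impossible under the
add-one permutation estimator, but possible in imported tables) are clamped
to the permutation floor 1/(n_perm + 1) with a warning. A pathway is
**focused** when at least two individual datasets give p < 0.01 *and* the
aggregate p is below 0.01; skipped tests enter as p = 1, keeping the degrees
of freedom constant across pathways. With exactly three datasets the
aggregate gate is implied by the two-hit rule (two p < 0.01 already force an
aggregate below 0.0052); the gate binds once more datasets dilute the
signal. Overlap significance between per-dataset result lists uses the
hypergeometric upper tail over the appropriate universe (369 pathways-scale,
gene-scale, or the n(n−1)/2 gene-pair universe), and top-k agreement scans
k over a grid with rank ties broken by name.

## Hub dynamics: constancy, retention, and two nulls

The **constancy rate** is the fraction of focused pathways whose hub is the
same gene in both conditions. The **retention rate** is per-gene: among
distinct baseline hubs (over all pathways) that are also DCGs, the fraction
that remain the perturbed-condition hub of at least one pathway they hubbed
at baseline; the complement are the **vanishing hubs**. Two nulls calibrate
these rates, both with lower-tail add-one p-values (the scientific claim is
that observed rates are unusually *low*): shuffling condition labels and
re-running the hub and DCG machinery; and shuffling the gene-to-pathway
annotation — every pathway's gene set replaced by a uniform draw of the same
size from the compendium universe (sizes preserved exactly, overlap between
pseudo-pathways allowed, the weakest reading of size-profile preservation).
Null constancy is computed over all pathways (the focused list is a
cross-dataset construct that has no analogue inside one permutation), while
the observed rate uses the focused list. Under annotation shuffling the DCG
list is not recomputed: DCG calling never sees the annotation.

## Crosstalk: a hypergeometric test on the decreased-link scaffold

The **scaffold** collects the correlation-decreased DCLs
(`decreased_positive` plus `diff_signed` with |r2| < |r1|), optionally
unioned over datasets. For a pathway pair, shared genes are removed from
both sides; with A′ and B′ the remainders, the observed count of scaffold
edges joining A′ to B′ is referred to the hypergeometric upper tail of
drawing |A′|·|B′| pair slots from all C(|universe|, 2) gene pairs containing
the scaffold's edges. Links inside the overlap of two pathways never count
as crosstalk. Raw p < 0.05 builds the map (no multiple-testing correction,
matching the convention for crosstalk maps; a BH switch exists but is off
by default), and the exported gene-level subnetwork is restricted to links
incident to DCGs or hubs.

## The synthetic generator

The generator draws each condition from a zero-mean multivariate normal
whose correlation matrix encodes: within-pathway equicorrelated blocks at a
per-class pair (ρ₁, ρ₂) (e.g. attenuated 0.8 → 0.1, the default; stable
classes for null studies); one hub gene per pathway whose correlation to
members is ρ + `hub_boost`, capped both at 0.99 and at the positive-definite
feasibility bound h ≤ sqrt((1 + (m−1)ρ)/m) for m members (a hub cannot be
more correlated with every member than the members' mutual correlation
permits); optional one-to-one cross-pathway gene couplings that decohere
(ρ_between per condition); zeros elsewhere. The matrix is repaired to
positive definiteness by eigenvalue clipping with diagonal renormalization,
and generation fails loudly if the repair moves any entry by more than 0.02
— infeasible targets are an error, not a silent distortion. Couplings are
one-to-one by construction: a dense biclique of strong cross-correlations
over weakly correlated blocks is not representable by any valid correlation
matrix, which the feasibility check would reject.

What the generator does *not* emulate: count noise and library-size effects
of real RNA-seq (values are Gaussian, mimicking log-scale normalized
expression), heavy-tailed or nonlinear dependence, overlapping pathways, and
the broad low-level inter-gene correlation of real transcriptomes (outside
planted blocks and couplings the population correlation is exactly zero).
Passing tests therefore demonstrate that the machinery recovers planted
first-order correlation structure, not that real data meet these
assumptions.

## Validation studies and problem sizes

The test suite and the acceptance script run these studies (sizes chosen to
make each property measurable at desk scale):

* **Attenuation recovery** — 20 replicates of the default generator (6
  pathways × 15 genes, 30 background genes, ρ 0.8 → 0.1, 50
  samples/condition). Planted pathways classify `dissolved` in ≈ 98% of
  cases. The decreased-positive share of DCLs is ≈ 70%: all intra-pathway
  DCLs are decreased, but the OR density rule also admits inter-pathway
  noise links through the condition-2 cutoff, and the per-bin top-fraction
  selection grants those bins their quota, yielding a floor of
  increased/negative calls. A global attenuation affecting *all* strong
  pairs (as in real tissue) would push the share higher; under this
  generator's zero inter-pathway correlation the share is structurally
  0.65–0.8.
* **Type-I error and uniformity** — 200 single-pathway null datasets
  (ρ identical across conditions), 200 permutations each: rejection at
  α = 0.05 lands near 0.05 and the p-values pass a Kolmogorov–Smirnov
  uniformity check.
* **Power** — 100 replicates of 0.8 → 0.2 attenuation with the default hub,
  1000 permutations: rejection at p < 0.05 in ≥ 95% of replicates.
* **Hub recovery** — 100 replicates, 15 genes, base ρ 0.5 with a 0.2 hub
  boost (0.5 is the largest base at which a full 0.2 boost stays inside the
  feasibility bound): the planted hub is reported in ~100% of replicates.
* **Crosstalk** — 50 replicates of two stable (ρ 0.45) pathways among eight,
  with three one-to-one couplings at 0.5 → 0. Stable blocks are the clean
  isolation design: the coupled pairs are then the only truly differential
  feature, and their x-bins are populated by persistent fold ≈ 1 pairs. Even
  so, measured detection power is low (~0.1): a decoupled pair's fold is
  0.5/|noise| (median ≈ 5 at 50 samples) while its bin's top-10% fold cutoff
  is set by one-condition noise flukes whose minimum correlation is near
  zero (folds 15 and far beyond), and those flukes mass at exactly the same
  x ≥ density-cutoff region where genuine links live. The magnitude axis
  cannot separate the two, so most planted couplings miss the envelope and
  the three-edge overlap needed for hypergeometric significance rarely
  materializes. The null-scaffold false-positive rate, by contrast, is well
  controlled (≤ 0.05 at nominal 0.05, conservative due to discreteness).
* **Conserved-hub saturation** — a stable-correlation generator with
  persistent hubs yields constancy = 1 and permutation p = 1 under both
  null schemes, and the add-one floor 1/(n_perm + 1) is attained when the
  observed rate undercuts every permuted rate.

## Numerical and design choices worth knowing

* **Quantile conventions.** The link-density cutoff is a k-th largest value
  with ties included (realized density ≥ target). The median-expression
  gene filter uses R's default interpolated quantile, so a 0.5 cut is a
  true median split; re-filtering an already-filtered matrix recomputes the
  percentile on the survivors and will thin further — the filter is a
  one-shot preprocessing step, not a projection.
* **Determinism.** Every randomized operation takes an explicit seed;
  pathway-level permutation streams are seeded per pathway name; the
  compendium ablation scan orders by (size decreasing, name), with the
  lexicographically later name treated as smaller on exact size ties.
* **Merging gene sets.** Identically named pathways merge onto the largest
  set, each other source contributing its extra genes only when it shares
  strictly more than 70% of its genes with the base; all qualifying sources
  contribute, applied in decreasing size order. Pairwise overlap ablation
  then discards the smaller pathway of any pair sharing strictly more than
  70% of the smaller set's genes.
* **Degenerate inputs.** Zero-variance genes are excluded with a warning;
  an all-zero correlation matrix yields uniform weights with a warning; a
  3-gene pathway has no second spanning tree (warning, first tree only);
  empty scaffolds and empty compendia are errors, an empty crosstalk map is
  a report.
* **Single-dataset runs** degrade the focused rule to the per-dataset
  threshold, since the two-dataset requirement is undefined.

## Known limitations

Pearson correlation only (the upstream pipelines this mirrors transform
expression to roughly Gaussian scales); no partial correlations, soft
thresholding, or alternative gene-set statistics; crosstalk detection
inherits the LFC envelope's insensitivity to isolated decoupled pairs, as
quantified above; and the permutation nulls assume exchangeable samples
within conditions (no covariate adjustment or batch structure).
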