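---
title: "Methods: cell-state resolution in xenograft single-cell RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-state resolution in xenograft single-cell RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scstate)
```

# The problem

Single-cell RNA-seq of patient-derived xenografts (PDX) mixes several
sources of variation that have nothing to do with the biological states one
wants to resolve: murine cells and multiplets from the host, per-library
sequencing depth and capture efficiency ("library complexity"), the cell
cycle, and the donor of origin. `scstate` implements a complete chain that
(i) filters libraries with species-ratio, depth and detected-gene criteria,
(ii) infers each cell's cell-cycle stage and a continuous circular phase,
(iii) regresses cell-cycle position and library complexity out of the
log-normalized expression, (iv) clusters the residuals with an SNN-graph
Louvain procedure, (v) detects cluster markers with a combined-p rule over
pairwise tests, and (vi) groups clusters into "superclusters" by their
normalized enrichment score (NES) profiles over genesets, extracting
supercluster-specific signatures.

# Quality control

Per library: the human/mouse read ratio must be at least
`species_ratio_min` (default 5; a library with zero mouse reads and any
human reads passes), strictly more than `human_reads_min` human reads
(default 100,000 — libraries *at* the threshold are removed), and a number
of detected genes inside the closed band `[genes_min, genes_max]` (defaults
2,346 and 9,884). The first failing filter, in the order species → depth →
gene band, is recorded as the rejection reason, so reasons partition the
rejected cells.

The absolute gene-band defaults correspond to keeping cells expressing
roughly 10–40% of a 23,459-gene transcriptome;
`gene_band_from_denominator()` rescales the band to any dataset via those
fractions, and `run_pipeline(adapt_gene_band = TRUE)` applies that
rescaling, since the absolute bounds are meaningless for a reduced
simulated transcriptome. Note the two conventions agree exactly only at
the lower bound; the published upper bound sits at 42% rather than 40% of
the denominator, and we treat the printed absolute values as authoritative
defaults.

PDG ("percentage of detected genes", the library-complexity covariate) is
`n_genes_detected / D` with `D` the number of unique genes detected in at
least one library of the input; `D` can be fixed explicitly for
cross-dataset comparability.

Kept libraries are scaled to `norm_total` (100k) summed counts and
transformed with `log(1 + x)`. Natural log is the default (matching the R
ecosystem the original analysis used); base 2 is available via
`log_base = "2"`. Per-cell scale invariance (doubling a cell's counts
changes nothing) is property-tested.

# Cell-cycle inference

Five stage scores (order `G1.S, S, G2, G2.M, M.G1`) are computed per cell
as the mean log-expression of stage genesets, then z-normalized across the
five stages within each cell. Cells are assigned to the stage whose
*expected profile* best correlates (Pearson) with their 5-score vector;
cells whose best correlation is below `cor_thr` (default 0.2) stay
unassigned, as do cells with zero score variance.

**Initial profiles.** The curated stage gene lists define which genes peak
when, but no numeric profiles. The default initial profile for stage *s*
is an indicator-like vector (+1 at *s*, −0.25 elsewhere, standardized);
it encodes nothing more than "peaks at its own stage" and is replaced by
data-driven profiles after one refinement iteration. Profiles are
user-overridable.

**Refinement.** Up to `refine_iter` (default 200) iterations alternate
profile re-estimation (the mean score vector of each stage's current
members; a stage that loses all members keeps its profile) with
reassignment. Numerical choice that matters: on unsynchronized populations
the score vectors form a *continuum* around a ring, and the
update/reassign map then has a neutrally stable rotational mode — after
the first informative iterations it slowly rotates all five stage windows
together (about a degree per iteration on the standard synthetic design),
which drifts the labels away from the geneset anchor without improving the
partition. The loop therefore stops when fewer than `tol` (default 1%) of
labels change in an iteration; `tol = 0` restores strict fixed-point
semantics. On blob-structured score data the refinement converges to the
blob partition in a handful of iterations either way (unit-tested).

**Continuous phase.** The 5-dimensional score vectors are projected on
their first two principal components and each cell's angle about the
centroid is taken as its phase θ. Orientation and origin are anchored by
the discrete labels: the plane is reflected if the stage circular means
run against cycle order, and rotated so the G1.S mean sits at θ = 0. Every
cell gets a phase, including unassigned ones. A four-label reporting map
(M.G1→G1, G1.S→G1/S, S,G2→S/G2, G2.M→G2/M) is provided as a documented
convention; the five-stage labels are primary.

# Covariate correction

The cell-cycle position enters the regression as `(sin θ, cos θ)` — a
single angle column would impose a spurious discontinuity at 2π, and the
continuous encoding exactly absorbs any first-harmonic cycle effect.
Discrete stage indicators are available via `encoding = "stage"`. PDG is
the third default covariate; columns are centred and constant columns
dropped with a warning. Per gene, ordinary least squares (the Gaussian
identity-link GLM) of expression on intercept + covariates yields
residuals that are exactly orthogonal to every covariate column
(assertable, and asserted, at 1e−8 of the data scale); regression is
idempotent. No count-model correction is attempted since the input is
log-normalized. Donor is deliberately *not* a default covariate — the
chain analyses donors jointly and lets biology mix them — but can be
passed through `extra`.

# Clustering

PCA treats cells as observations with genes centred (optionally scaled);
component signs are fixed so each component's largest-magnitude loading is
positive, making the embedding deterministic. The SNN graph connects two
cells iff their neighbourhoods — self plus the `k` nearest by Euclidean
distance, ties broken by cell index — intersect, weighted by Jaccard
overlap. Jaccard was chosen over rank-based weighting because it admits
exact small-case oracles (the test-suite enumerates neighbourhoods by
hand). Louvain (weighted modularity, resolution 1 by default) runs with a
seeded sweep order, so a fixed seed fixes the labels; an edgeless graph
yields singletons. The default graph input is the top-`n_pcs` PCA of the
residuals rather than a stochastic 2-D embedding; external 2-D coordinates
can be clustered through the CLI by passing them as the expression input.

# Markers

For every ordered cluster pair, a per-gene Welch t-test (Satterthwaite
degrees of freedom; a pooled-variance option exists) gives p-values and
logFC = mean(target) − mean(other). Genes with zero variance in both
groups get p = 1, logFC = 0. Per gene, the m pairwise p-values are
Holm-corrected, and the combined p is the k-th smallest Holm value with
k = ⌈`min_prop` · m⌉ — small exactly when the gene is differential in at
least a `min_prop` fraction of comparisons ("some" rule). The literal
"minimum of the smallest 20%" reading degenerates to the overall minimum
("any" rule) and contradicts the rule's own gloss; it is available via
`rule = "any"`. FDR is Benjamini–Hochberg across genes within a cluster;
the summary logFC is the logFC of the comparison whose Holm p equals the
combined p (ties towards the largest |logFC|; a mean-across-comparisons
option exists). Ranked lists (all genes by summary logFC) feed the
enrichment step; top-`top_n_deg` (250) lists at FDR < 0.05 feed the
signatures.

# Enrichment and superclusters

The enrichment score is the signed maximum deviation of the weighted
Kolmogorov–Smirnov running sum (hits weighted by |score|^`weight_exp`,
default 1; misses −1/(N − N_hits)). NES normalizes by the mean |ES| of
matching-sign permutation nulls from `n_perm` (default 2,000) random
same-size genesets drawn from the ranked genes — a gene-permutation null,
matching preranked usage; p = (1 + #{|null| ≥ |ES|, same sign}) /
(1 + #same-sign). Same-size genesets share null distributions within a
cluster for speed, and the null path is computed from hit positions only
(O(m) per permutation), verified against the full running sum in the
tests.

Per geneset, the maximum |NES| across clusters ranks the genesets; the top
25 span the NES space in which clusters are grouped by hierarchical
agglomerative clustering (average linkage, Euclidean) cut into
`n_superclusters` (3). Whether the original grouping was algorithmic or
visual is not stated; hierarchical clustering is this package's
operationalization. Supercluster letters follow the dendrogram order, or
increasing mean NES over user-named proliferation genesets when provided.
A supercluster's signature is the intersection of its upregulated
top-lists over all its own contrasts minus every gene in any other
supercluster's up-lists — signatures are disjoint by construction and are
emitted as plain gene lists for external survival tools.

# The synthetic world

`simulate_dataset()` generates the data every downstream claim is tested
against. Expected log expression of gene g in cell c is

```
log(baseline_g) + donor[g, d(c)] + state[g, s(c)] + A · cos(θ_c − peak_g)
```

with the last term for cycle-regulated genes only; counts are negative
binomial and then binomially thinned by a per-cell capture efficiency
drawn uniformly from `pdg_range`, which induces the detected-gene (PDG)
gradient. The five stage genesets are the cycle genes binned by peak phase
into equal 72° arcs. Mouse contamination exists only in the read-statistics
table (a low human/mouse ratio), mirroring a species-screen report — the
species filter operates on the table, not on counts.

Stated-world defaults: 2,000 genes × 500 cells, 3 donors, 3 states
(logFC 1.0 on 5% of genes each), 15% cycle genes with amplitude 1.5,
capture 0.2–0.6. Where the design was open, constants were chosen once for
realism and recoverability and are deliberately arbitrary:
`baseline_mean = 2` with lognormal (sdlog 1) spread and NB dispersion 0.4
(full-length/C1-like counts), `donor_effect_sd = 0.15` — large enough that
donors are visible in the embedding, small enough that a 100-gene state
effect is not swamped by a transcriptome-wide donor shift — and marker/
cycle roles planted on the expressed half of the transcriptome, because a
transcriptionally silent gene cannot act as a marker at any sample size a
desk-scale test can afford. Emitted read depths are scaled to an expected
~400k reads/cell regardless of transcriptome size so the fixed 100k QC
floor stays meaningful in scaled-down designs.

What the generator does *not* emulate — and therefore what a green test
does not establish: empirical dropout/batch calibration (splatter-style),
doublet expression profiles (only the read-ratio proxy), donor-specific
cell-state composition, and any real geneset content (tests use
generator-emitted and synthetic genesets; Hallmark collections must be
supplied by the user as GMT).

One stated-world consequence worth knowing: applying the 10–40%
detected-gene band to the simulator (whose healthy cells span ~20–55%
detection) removes roughly half the cells. This is the faithful behaviour
of the published rule on this world, not a bug; downstream recovery is
tested on the surviving cells.

# Numerical choices and degenerate inputs

* Stage-assignment ties go to the earlier stage in cycle order; ties are
  deterministic.
* Degenerate (all-equal) score vectors are flagged, kept at zero, and
  excluded from assignment; the circular fit requires ≥ 3 non-degenerate
  cells.
* Rank-deficient covariate designs abort with the collinear columns named;
  constant columns are dropped (warning) before that check.
* PCA sign convention: largest-|loading| positive.
* kNN distance ties break by cell index; SNN weights are in (0, 1].
* `combine_some` with m = 1 returns the single Holm p; `min_prop = 1` is
  the "all" rule.
* ES with a geneset covering the whole list is +1; zero total hit weight
  falls back to unweighted increments; permutation p is guarded at 1 when
  no matching-sign nulls exist (with a warning).
* All stochastic steps (simulation, Louvain sweep order, permutation
  nulls) are seeded; fixed seeds give bit-identical results, which the
  tests assert.

# Known limitations

* The cell-cycle caller assumes the five stage genesets are informative in
  the input matrix; it errors on stages with no matching genes rather than
  guessing.
* The refinement tolerance trades exact fixed-point semantics for
  anchoring stability (see above); with `tol = 0` the literal iteration is
  available and occasionally rotates labels on continuum data.
* Supercluster letters are stable only given the dendrogram or an explicit
  proliferation-geneset ordering.
* No pseudobulk or covariate-adjusted DE beyond operating on residuals;
  no survival analysis — signature lists are produced for external tools.
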