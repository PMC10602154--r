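---
title: "Regulatory-domain analysis of population-scale chromatin accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regulatory-domain analysis of population-scale chromatin accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Case/control ATAC-seq cohorts measure chromatin accessibility at hundreds of
thousands of open-chromatin regions (OCRs, "peaks") across hundreds of
donors. Beyond per-peak differential testing, the inter-individual
correlation structure of accessibility is itself informative: genomically
contiguous peaks whose accessibility co-varies across donors behave as
*cis*-regulatory domains (CRDs), and disease-associated CRDs in turn
cluster — possibly across chromosomes — into *trans*-regulatory domains
(TRDs). Layered on top sit three sample-level analyses: a per-sample disease
pseudotime derived from the disease-associated peaks, set-enrichment scores
of bulk-derived peak sets in single-cell ATAC, and polygenic risk scores
restricted to the variants inside a domain's peaks.

`regdomains` implements this whole chain as composable functions plus a
one-config `run_pipeline()`, and ships a synthetic-data generator that
plants recoverable ground truth at every level, so each stage — and the
pipeline end to end — is testable without any restricted-access cohort.

# The synthetic cohort

`sim_config()` fixes the study conditions; all generators are deterministic
functions of it (one labelled RNG stream per output object, so adding cells
or variants never perturbs the bulk matrix).

**Bulk accessibility.** Log2-scale values come from a Gaussian copula whose
correlation matrix is block-diagonal along chromosomes: each planted CRD
shares a latent factor giving pairwise within-CRD correlation
`within_crd_correlation` (default 0.7), and CRD factors of the same TRD are
coupled so the correlation between CRD *mean signals* targets
`trd_cross_correlation` (default 0.6; the per-CRD loading is solved from
the CRD size so the target refers to mean signals, not raw peaks). TRDs are
mutually independent — the minimal structure sufficient for recovery tests.
The exponential of the matrix is the strictly positive count-scale view;
the pipeline consumes the log scale directly because the normalization of
the emulated assay is a free choice (`normalize_counts()` provides CPM +
log2(x+1) for count input).

**Disease effect as a liability continuum.** Every sample carries a latent
severity; affected peaks (default 10% of the universe, filled into the
disease TRD first, remainder flagged background) receive a mean shift
`disease_effect_size * severity`. Case labels are drawn with probability
proportional to `exp(severity)`, so cases sit at the perturbed pole while
controls spread across the mild end — matching the interpretation of
disease stages in which controls occupy early stages rather than a
zero-signal point mass. A consequence worth stating: the case/control mean
shift at an affected peak is `disease_effect_size` times the case−control
severity gap (about one SD under the default sampling), not
`disease_effect_size` itself.

**Genetic liability.** Dosages are Binomial(2, MAF); weights are
concentrated (in sign and magnitude) in variants placed inside affected
peaks. The standardized weighted dosage sum is the true genetic score, and
severity equals `c * score + sqrt(1 - c^2) * noise` with
`c = severity_prs_correlation`. Two deliberate design points:

* *Causal order.* The genetic score is drawn first and severity derived
  from it — a liability-threshold-style model. The alternative (add noise
  to the score until it matches an independent severity) cannot create the
  intended correlation.
* *Variant counts.* At desk scale (n = 300) the Nagelkerke pseudo-R² of a
  null score is biased upward by order 1/n, so a domain hosting only a
  handful of variants can win a variance-per-variant comparison by the
  division alone. The generator therefore concentrates the liability
  signal in relatively few weighted variants (15% of the total) and
  spreads unweighted variants broadly (70% in non-affected peaks), giving
  every TRD on the order of a hundred variants — the same order as the
  annotation-restricted scores the package emulates.

**Single cell.** Cells get a type, a donor and a developmental stage
group; counts are Poisson around depth-scaled per-peak rates, with a 2x
rate for each type's planted signal peaks (type A's signal peaks are drawn
from the disease TRD). Donors carry a lognormal compositional jitter shared
by their cells — this is the donor random effect the one-vs-rest mixed
model is built to absorb; without it the random intercept is genuinely
zero and every fit is singular.

**What the generator does not emulate:** fragment-level counts, GC and
mappability biases, LD between variants, batch structure beyond a single
binary covariate, spatially varying peak density, doublets or ambient
signal in the single-cell layer. Passing tests therefore demonstrate
correctness of the statistical machinery on its stated model, not
robustness to these real-data phenomena.

# CRD assembly

Per chromosome, clusters of peaks are merged agglomeratively with the
constraint that only genomically adjacent clusters may merge; similarity is
the mean cross-pair Pearson correlation (ties break to the leftmost pair,
making the tree deterministic). A subtree is accepted as a CRD when

1. it has at least `min_peaks` members (default 3),
2. its mean internal pairwise correlation is at least `r_threshold`
   (default 0.3), and
3. the mean cross-correlation between its two child clusters (its merge
   similarity) is also at least `r_threshold`.

CRDs are the maximal accepted subtrees. Condition 3 deserves a note: with
conditions 1–2 alone, a tightly correlated block sits far above the
threshold and can absorb flanking background peaks while its internal mean
stays above `r_threshold`; in simulations this inflates domains by several
noise peaks each and drops peak-level recovery (ARI ≈ 0.68 instead of 1).
The child-link condition rejects exactly these heterogeneous nodes, and on
instances small enough to enumerate, the calls coincide with a brute-force
oracle that recomputes the same rule naively and checks every call against
the exhaustive list of valid contiguous segments.

The defaults (`r_threshold = 0.3`, `min_peaks = 3`) are exposed in the
configuration; behavior is pinned by recovery tests on the synthetic
cohort rather than by published thresholds, which the emulated study does
not state.

# Differential testing

`differential_peaks()` fits `accessibility ~ group + covariates` per peak
by ordinary least squares (a single QR factorization for all peaks) and
reports the group-contrast t, two-sided p and BH FDR; `moderated = TRUE`
swaps in limma's empirical-Bayes moderated t behind the same interface.
Constant peaks are reported as null (`log2fc = 0, p = 1`). The up/down
partition of the FDR < 0.05 set is by fold-change sign; exact zeros belong
to neither side.

The two-stage differential-CRD test concretizes "screen, then confirm":

* **Stage 1 (screening).** A two-sample Hotelling T² omnibus test across a
  CRD's member peaks (exact F; falls back to the mean-signal t when the
  member count approaches the sample count), BH-adjusted across CRDs at
  `alpha`.
* **Stage 2 (confirmation).** A pooled-variance t on the CRD mean signal,
  Bonferroni-corrected within the screened set.

A CRD is called differential only if both stages pass, which keeps the
false-discovery proportion at or below the screening level by
construction; with a single screened CRD the procedure reduces exactly to
a t test on its mean signal. Whether screening should operate on member
peaks or on domain principal components is genuinely open; member-peak
screening is this package's concretization.

# TRD discovery and the Gamma statistic

Significant CRDs are clustered by average-linkage (complete by flag) on
the distance 1 − r of their per-sample mean signals. For every candidate
k the tree is cut and the Goodman–Kruskal (Baker–Hubert) Gamma computed:
concordance between pairwise distances and co-membership, with exact ties
contributing to neither count — the deterministic Baker–Hubert convention.
The selected k maximizes Gamma, smallest k on ties; cuts where Gamma is
undefined (fewer than two within- or between-pairs) are recorded as NA and
never win. TRDs are renumbered by decreasing size.

A caution the test suite documents: Gamma evaluated on labels *derived
from clustering the same distances* is optimistic in unstructured data
(near-tie pairs become small within-cluster distances), so a high maximum
Gamma alone is not evidence of modules; the calibrated property is that
Gamma is near zero for labels random with respect to the distances.

`trd_direction_profile()` counts up/down CRDs per TRD and flags TRDs whose
up fraction exceeds 0.75 (configurable) as predominantly upregulated — the
signature by which the disease TRD is recognized.
`fold_change_correlation()` is the Spearman correlation of two per-peak
fold-change vectors over shared peaks (n ≥ 10), the tool for asking
whether a TRD's disease upregulation tracks, e.g., developmental
upregulation.

# Disease staging

`embed_samples()` restricts to a signature peak set, z-scores per peak,
builds a tie-inclusive symmetric kNN graph (default 15 neighbours) with an
adaptive Gaussian kernel (per-sample bandwidth = distance to the k-th
neighbour), and takes the top nontrivial right eigenvectors of the
row-normalized transition operator, scaled by their eigenvalues
(a diffusion map, default 10 components). Tie-inclusive neighbourhoods
make duplicated samples exact embedding duplicates. A disconnected graph
is an error with the advice to raise `n_neighbors`.

Diffusion pseudotime is the Euclidean distance from a root sample in the
component space with each (unit-normalized) component weighted by
λ/(1−λ); the unit normalization is pinned so that a dense-matrix oracle
taking right eigenvectors of the non-symmetric transition matrix directly
reproduces the package path to 1e-8. The root defaults to the control
sample with the lowest mean signature accessibility — the least-perturbed
pole, so "early stage" means what it says; it is overridable by ID.
Pseudotime is min–max scaled to [0, 1] for comparability.

Stages are Leiden communities (modularity objective, fixed seed,
resolution 1 by default) on the affinity graph, relabeled 1..K by
ascending mean pseudotime. Associations reported: logistic case ~
pseudotime (OR per SD), the linear model stage ~ PRS + Age + Age² + Sex,
and Spearman's ρ of pseudotime with PRS.

One identifiability limitation, visible in the synthetic severity-gradient
scenario: when all signature peaks also share a strong trans factor
(cross-CRD coupling ~0.6), the leading diffusion components mix that
factor with severity and the pseudotime–severity correlation degrades.
The staging validation therefore uses a weakly coupled background (0.3);
on real data an analogous global factor (e.g. a technical axis) would need
removing by residualization first.

# Single-cell enrichment

`cell_set_zscores()` compares, per cell, the observed fraction of depth in
the target peaks against B background sets matched to the target on
quantile bins of depth-normalized mean accessibility
(`z = (obs − mean_bg)/sd_bg`). Bins default to roughly five peaks each (at
least ten bins): coarse decile-style bins leave an accessibility-mismatch
offset of several tenths of a z unit for a random target set, while fine
bins bring random-set calibration inside ±0.2. The construction follows
the deviation-score idea of chromVAR-style methods but matches on
accessibility only, since the synthetic data has no sequence; `n_bins` is
exposed, and GC matching would slot in as an additional binning covariate.

`celltype_mixed_model()` fits `z ~ 1[cell type = focal] + (1 | donor)` and
reports the Wald p of the fixed effect; a singular fit or a single donor
falls back to OLS with donor-cluster-robust (or heteroskedasticity-robust)
standard errors, flagged in the output. `celltype_enrichment_scan()` runs
all (type × stage-group) combinations under one BH adjustment, and
`enrichment_set_contrast()` implements the paired within-cell comparison
of two peak sets inside a focal type.

# Interval-restricted polygenic scores

`subset_variants_by_intervals()` keeps variants whose 1-based position
falls inside a peak subset, honoring the BED fence: a variant at `pos` is
inside `[start, end)` iff `start + 1 ≤ pos ≤ end`. `score_samples()` is
the weighted dosage sum with per-variant mean imputation (variants over
20% missing are dropped). `prs_association()` standardizes the score,
fits logistic case ~ score, and reports OR per SD, Wald SE/p, Nagelkerke
pseudo-R² (the standard "variance explained" metric for case/control
polygenic scores) and variance explained per variant.
Complete separation triggers a penalized refit via half-weight
pseudo-observations. The headline qualitative property on synthetic data:
the disease TRD ranks first on variance per variant against the other
TRDs and the genome-wide score.

# Numerical choices and degenerate inputs

* Merge ties in the CRD tree: leftmost pair; Gamma ties: excluded from
  both counts; Gamma-maximizing k ties: smallest k.
* Hotelling screening falls back to the mean-signal t when the pooled
  covariance cannot support the exact F; a near-singular pooled
  covariance gets a 1e-8 ridge.
* Eigenvector signs are fixed by making each component's
  largest-magnitude entry positive.
* Constant peaks, constant CRD signals, single communities, flat stages,
  missing PRS, single donors and separated logistic fits all have defined
  behavior (convention, drop-with-warning, warning-and-skip, error, skip,
  robust fallback, penalized fallback respectively).
* Residualization refuses to remove `diagnosis` and reports collinear
  columns by name; it is idempotent to 1e-10.

# Problem sizes used in validation

The shipped checks run the reference cohort (300 samples, 2 × 400 peaks,
20 CRDs of 8–25 peaks, 3 TRDs), 10–50 seed replicates per calibration
property, 200 random instances per brute-force oracle, and a 3,000-peak
fold-change correlation — sizes chosen so the full suite exercises every
stage at statistically meaningful scale on a single CPU in minutes. The
test suite and `scripts/acceptance.R` compute every number this vignette
alludes to; nothing here is asserted beyond what they measure.
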