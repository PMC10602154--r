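# regdomains

Analysis of population-scale ATAC-seq chromatin accessibility organized
into regulatory domains. The package is aimed at statistical-genomics
analysts working with case/control accessibility cohorts (samples ×
peaks matrices with donor metadata) who want to go beyond per-peak
differential testing and ask how disease signal is structured — along
the genome, across the genome, across donors, across cell types, and
across the genetic risk architecture.

## What it computes

Writing $y_{sp}$ for log-accessibility of peak $p$ in sample $s$:

- **Differential OCRs** — per-peak OLS fit of
  $y_{sp} \sim \text{group} + \text{covariates}$, BH-adjusted two-sided
  t tests, and the up/down partition of the FDR < 0.05 set by the sign
  of $\log_2 \text{FC}$ (optional limma moderated-t engine).
- **Cis-regulatory domains (CRDs)** — adjacency-constrained
  agglomerative clustering of peaks by inter-individual Pearson
  correlation; a CRD is a maximal subtree with mean internal correlation
  ≥ $r$ and child-link correlation ≥ $r$ (default $r = 0.3$), size ≥ 3.
- **Differential CRDs** — a two-stage test: Hotelling $T^2$ omnibus
  screening across member peaks under BH control, then a confirmation t
  test on the domain mean signal, Bonferroni within the screened set.
- **Trans-regulatory domains (TRDs)** — average-linkage clustering of
  significant CRDs on $1 - r$ of their mean signals, with the number of
  clusters selected by the Goodman–Kruskal (Baker–Hubert) Gamma
  statistic $\Gamma = (s^+ - s^-)/(s^+ + s^-)$; per-TRD up/down
  profiles flag the predominantly upregulated disease TRD.
- **Disease pseudotime** — diffusion-map embedding of samples on the
  upregulated signature, Leiden staging, diffusion pseudotime
  (components weighted by $\lambda/(1-\lambda)$ from a root control),
  and the associations case ~ pseudotime, stage ~ PRS + Age + Age² +
  Sex, Spearman(pseudotime, PRS).
- **Single-cell enrichment** — per-cell deviation z-scores of a peak
  set against accessibility-matched background sets, and the
  one-vs-rest mixed model `z ~ celltype + (1 | donor)`.
- **TRD-stratified polygenic scores** — interval-restricted weighted
  dosage sums, logistic OR per SD, Nagelkerke pseudo-R², and variance
  explained per variant.

A synthetic-data generator (`sim_config()`, `simulate_bulk()`,
`simulate_single_cell()`, `simulate_genotypes()`) plants recoverable
CRD/TRD structure, a severity-scaled disease effect, genetic liability
and cell-type signal, so the whole chain is testable end to end; see the
methods vignette (`vignettes/regulatory-domains.Rmd`) for the model and
its limitations.

## Worked example

```r
library(regdomains)

cfg <- sim_config(seed = 42)
sim <- simulate_bulk(cfg)
sim
#> BulkSimulation: 300 samples x 800 peaks; 338 peaks in 20 planted CRDs

diff <- differential_peaks(sim$matrix, covariates = c("age", "sex", "batch"))
diff
#> DifferentialResult: 800 peaks; 81 at FDR < 0.05 ( 81 up / 0 down )

dom <- build_crds(sim$matrix, sim$peaks)
dom
#> DomainSet: 20 CRDs covering 338 of 800 peaks

cd <- two_stage_crd_test(dom, sim$matrix)
cd
#> CrdDifferential: 20 CRDs; 7 differential at the two-stage FDR 0.05

trd <- build_trds(cd, dom, k_range = 2:10)
trd_direction_profile(trd, cd)
#>   trd n_crds n_up n_down up_fraction predominantly_up
#> 1   1      6    6      0           1             TRUE
#> 2   2      1    1      0           1             TRUE

st <- disease_stage(sim$matrix, direction_partition(diff)$up, seed = 42)
stage_associations(st, sim$matrix$metadata)
#> case ~ pseudotime: OR/SD = 2.406 (p = 5.33e-10)
#> stage ~ PRS + Age + Age^2 + Sex: beta = 0.465 (p = 1.16e-12, n = 300)
#> Spearman(pseudotime, PRS): rho = 0.370 (p = 3.73e-11)
```

Reading the output: the generator planted 20 correlated peak blocks, of
which the caller recovers all 20; the disease effect sits in one TRD,
whose CRDs pass the two-stage test and come out uniformly upregulated;
samples ordered by diffusion pseudotime separate cases from controls
(odds ratio 2.4 per SD of pseudotime), and the inferred stages track the
simulated polygenic score (β = 0.465) — the planted
severity–liability coupling, recovered from the matrix alone.

`run_pipeline(config, output_dir)` executes the same chain from one
(YAML/JSON or list) configuration and writes BED/TSV/MTX/JSON outputs
plus a manifest of parameters and MD5 hashes; re-running a config
reproduces identical hashes.

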