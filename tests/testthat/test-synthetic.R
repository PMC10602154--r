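test_that("identical configurations give bit-identical simulations", {
  cfg <- sim_config(n_samples = 60, n_cases = 20, peaks_per_chromosome = 60,
                    crd_sizes = c(5L, 6L), n_trds = 2L, n_cells = 150,
                    n_variants = 80, seed = 9)
  a <- simulate_bulk(cfg)
  b <- simulate_bulk(cfg)
  expect_identical(a$matrix$values, b$matrix$values)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_single_cell(cfg, a$truth)$counts,
                   simulate_single_cell(cfg, b$truth)$counts)
  ga <- simulate_genotypes(cfg, a$peaks, a$truth)
  gb <- simulate_genotypes(cfg, b$peaks, b$truth)
  expect_identical(ga$dosages, gb$dosages)
  expect_identical(ga$weights, gb$weights)
})

test_that("configuration invariants are validated with the field named", {
  expect_error(sim_config(n_cases = 300, n_samples = 300), "n_cases")
  expect_error(sim_config(within_crd_correlation = 1), "within_crd_correlation")
  expect_error(sim_config(trd_cross_correlation = 0), "trd_cross_correlation")
  expect_error(sim_config(crd_sizes = rep(30L, 30), peaks_per_chromosome = 100),
               "crd_sizes")
  expect_error(sim_config(n_cell_types = 40), "label space")
  expect_error(sim_config(covariate_effects = c(smoking = 1)),
               "covariate_effects")
  # a zero severity-PRS coupling is a legitimate null configuration
  expect_s3_class(sim_config(severity_prs_correlation = 0), "SimConfig")
})

test_that("copula hits the planted within-CRD correlation target", {
  cfg <- sim_config(n_samples = 300, peaks_per_chromosome = 50,
                    n_chromosomes = 1, crd_sizes = 10L, n_trds = 1L,
                    within_crd_correlation = 0.9, disease_effect_size = 0,
                    covariate_effects = c(), seed = 3)
  sim <- simulate_bulk(cfg)
  ids <- names(sim$truth$peak_to_crd)[!is.na(sim$truth$peak_to_crd)]
  C <- cor(sim$matrix$values[, ids])
  r_hat <- mean(C[upper.tri(C)])
  expect_gt(r_hat, 0.8)
  expect_lt(r_hat, 0.95)
})

test_that("cross-CRD correlation of same-TRD mean signals hits its target", {
  cfg <- sim_config(n_samples = 400, crd_sizes = rep(12L, 12), n_trds = 2L,
                    trd_cross_correlation = 0.6, disease_effect_size = 0,
                    covariate_effects = c(), seed = 5)
  sim <- simulate_bulk(cfg)
  sig <- sapply(seq_along(cfg$crd_sizes), function(c) {
    rowMeans(sim$matrix$values[, names(sim$truth$peak_to_crd)[
      !is.na(sim$truth$peak_to_crd) & sim$truth$peak_to_crd == c],
      drop = FALSE])
  })
  for (t in 1:2) {
    Ct <- cor(sig[, sim$truth$crd_to_trd == t])
    expect_lt(abs(mean(Ct[upper.tri(Ct)]) - 0.6), 0.05)
  }
  # TRDs themselves are independent
  C12 <- cor(sig[, sim$truth$crd_to_trd == 1], sig[, sim$truth$crd_to_trd == 2])
  expect_lt(abs(mean(C12)), 0.1)
})

test_that("a zero disease effect yields calibrated per-peak null tests", {
  cfg <- sim_config(n_samples = 200, n_cases = 100, n_chromosomes = 2,
                    peaks_per_chromosome = 1000, crd_sizes = c(3L, 3L),
                    disease_effect_size = 0, covariate_effects = c(), seed = 2)
  sim <- simulate_bulk(cfg)
  d <- differential_peaks(sim$matrix)
  expect_gt(mean(d$p < 0.05), 0.03)
  expect_lt(mean(d$p < 0.05), 0.07)
})

test_that("case severity stochastically dominates control severity", {
  for (s in 1:3) {
    sim <- simulate_bulk(sim_config(seed = s))
    sev <- sim$truth$sample_severity
    case <- sim$matrix$metadata$diagnosis == "case"
    expect_gt(mean(sev[case]), mean(sev[!case]))
    expect_gt(suppressWarnings(
      stats::wilcox.test(sev[case], sev[!case], alternative = "greater")$statistic),
      sum(case) * sum(!case) / 2)
  }
})

test_that("affected peaks sit in the disease TRD or are flagged background", {
  sim <- simulate_bulk(sim_config(fraction_affected_peaks = 0.4, seed = 4))
  aff <- sim$truth$affected_peaks
  in_crd <- sim$truth$peak_to_crd[aff$peak_id]
  disease_crds <- which(sim$truth$crd_to_trd == 1)
  expect_true(all(in_crd[!aff$background] %in% disease_crds))
  expect_true(all(is.na(in_crd[aff$background])))
})

test_that("the count-scale view of the bulk matrix is strictly positive", {
  sim <- simulate_bulk(sim_config(n_samples = 40, n_cases = 10,
                                  peaks_per_chromosome = 50,
                                  crd_sizes = c(4L, 4L), seed = 6))
  expect_true(all(is.finite(sim$matrix$values)))
  expect_true(all(2^sim$matrix$values > 0))
})

test_that("single-cell generator plants cell-type signal and positive depth", {
  hits <- 0L
  for (s in 1:5) {
    cfg <- sim_config(n_samples = 40, n_cases = 10, peaks_per_chromosome = 100,
                      crd_sizes = c(8L, 8L), n_trds = 1L, n_cells = 400,
                      celltype_signal_fraction = 0.1, seed = s)
    sim <- simulate_bulk(cfg)
    sc <- simulate_single_cell(cfg, sim$truth)
    expect_true(all(Matrix::rowSums(sc$counts) > 0))
    sig <- sim$truth$celltype_signal_peaks[["A"]]
    frac <- Matrix::rowSums(sc$counts[, sig, drop = FALSE]) /
      Matrix::rowSums(sc$counts)
    mt <- tapply(frac, sc$cells$cell_type, mean)
    if (mt[["A"]] > max(mt[names(mt) != "A"])) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("zero celltype_signal_fraction leaves type means at noise level", {
  cfg <- sim_config(n_samples = 40, n_cases = 10, peaks_per_chromosome = 100,
                    crd_sizes = c(8L, 8L), n_trds = 1L, n_cells = 500,
                    celltype_signal_fraction = 0, seed = 8)
  sim <- simulate_bulk(cfg)
  sc <- simulate_single_cell(cfg, sim$truth)
  set.seed(1)
  target <- sample(colnames(sc$counts), 30)
  frac <- Matrix::rowSums(sc$counts[, target, drop = FALSE]) /
    Matrix::rowSums(sc$counts)
  fit <- stats::aov(frac ~ cell_type, data = cbind(sc$cells, frac = frac))
  expect_gt(summary(fit)[[1]][["Pr(>F)"]][1], 0.001)
})

test_that("dosages live on {0,1,2} and the liability coupling is honored", {
  cfg <- sim_config(n_samples = 500, n_cases = 150,
                    severity_prs_correlation = 0.5, seed = 11)
  sim <- simulate_bulk(cfg)
  geno <- simulate_genotypes(cfg, sim$peaks, sim$truth)
  expect_true(all(geno$dosages %in% 0:2))
  r <- cor(sim$truth$sample_prs_true, sim$truth$sample_severity)
  expect_gt(r, 0.4); expect_lt(r, 0.6)
  # uncoupled configuration: correlation collapses to noise
  cfg0 <- sim_config(n_samples = 500, n_cases = 150,
                     severity_prs_correlation = 0, seed = 11)
  sim0 <- simulate_bulk(cfg0)
  expect_lt(abs(cor(sim0$truth$sample_prs_true, sim0$truth$sample_severity)),
            0.15)
  # weights concentrate inside affected peaks
  w <- geno$weights
  aff <- sim$truth$affected_peaks$peak_id
  pk <- as.data.frame(sim$peaks)
  gr_a <- GenomicRanges::GRanges(pk$chrom[pk$peak_id %in% aff],
                                 IRanges::IRanges(pk$start[pk$peak_id %in% aff] + 1L,
                                                  pk$end[pk$peak_id %in% aff]))
  gr_v <- GenomicRanges::GRanges(w$chrom, IRanges::IRanges(w$pos, w$pos))
  inside <- GenomicRanges::countOverlaps(gr_v, gr_a) > 0
  expect_gt(mean(abs(w$weight[inside])), 10 * mean(abs(w$weight[!inside])))
})
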