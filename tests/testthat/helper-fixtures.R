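# Shared fixture builders; everything is generated in code at test time.

# Minimal AccessibilityMatrix around a bare values matrix.
make_am <- function(values, diagnosis = NULL, extra = NULL) {
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("S%04d", seq_len(nrow(values)))
  }
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("p%05d", seq_len(ncol(values)))
  }
  meta <- data.frame(sample_id = rownames(values), stringsAsFactors = FALSE)
  if (!is.null(diagnosis)) {
    meta$diagnosis <- factor(diagnosis, levels = c("control", "case"))
  }
  if (!is.null(extra)) meta <- cbind(meta, extra)
  accessibility_matrix(values, meta)
}

# Evenly spaced PeakSet on one chromosome.
make_peaks <- function(p, chrom = "chr1", width = 500L, gap = 1500L) {
  start <- seq(0L, by = width + gap, length.out = p)
  new_peak_set(data.frame(chrom = chrom, start = start, end = start + width,
                          peak_id = sprintf("p%05d", seq_len(p))))
}

# Hand-built DomainSet + matrix with n_crds blocks of iid N(0,1) peaks and
# optional case shift delta on the first n_sig CRDs (group halves).
make_null_domains <- function(n, n_crds, size, delta = 0, n_sig = 0, seed = 1) {
  set.seed(seed)
  p <- n_crds * size
  vals <- matrix(rnorm(n * p), n,
                 dimnames = list(sprintf("S%04d", 1:n), sprintf("p%05d", 1:p)))
  g <- rep(c("control", "case"), each = n / 2)
  if (n_sig > 0) {
    aff <- seq_len(n_sig * size)
    vals[g == "case", aff] <- vals[g == "case", aff] + delta
  }
  crd_ids <- sprintf("CRD%04d", 1:n_crds)
  memb <- setNames(rep(crd_ids, each = size), colnames(vals))
  dom <- structure(list(
    domains = data.frame(crd_id = crd_ids, chrom = "chr1",
                         start = seq_len(n_crds) * 1000L,
                         end = seq_len(n_crds) * 1000L + 500L,
                         n_peaks = size,
                         mean_internal_correlation = NA_real_,
                         stringsAsFactors = FALSE),
    membership = memb,
    signal = sapply(split(colnames(vals), memb)[crd_ids],
                    function(cols) rowMeans(vals[, cols, drop = FALSE]))
  ), class = "DomainSet")
  list(d = dom, m = make_am(vals, diagnosis = g))
}

# Random correlation-like matrix for oracle instances: sample data then
# take its empirical correlation (always a valid correlation matrix).
make_random_corr <- function(p, n = 40, block = NULL, rho = 0.8) {
  X <- matrix(rnorm(n * p), n)
  if (!is.null(block)) {
    f <- rnorm(n)
    for (j in block) X[, j] <- sqrt(rho) * f + sqrt(1 - rho) * X[, j]
  }
  cor(X)
}

# CRD-signal matrix with planted TRD blocks (signal-level simulation).
make_trd_signals <- function(n = 300, n_trds = 3, crds_per_trd = 15,
                             cross = 0.6, seed = 1) {
  set.seed(seed)
  truth <- rep(seq_len(n_trds), each = crds_per_trd)
  f <- matrix(rnorm(n * n_trds), n)
  sig <- sapply(seq_along(truth), function(c) {
    sqrt(cross) * f[, truth[c]] + sqrt(1 - cross) * rnorm(n)
  })
  colnames(sig) <- sprintf("CRD%04d", seq_along(truth))
  list(signal = sig, truth = truth)
}

# Adjusted Rand index (mclust when present, else a direct computation so
# the suite has no hard dependency on it).
ari <- function(a, b) {
  if (requireNamespace("mclust", quietly = TRUE)) {
    return(mclust::adjustedRandIndex(a, b))
  }
  tab <- table(a, b)
  nij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2)); bj <- sum(choose(colSums(tab), 2))
  nn <- choose(sum(tab), 2)
  (nij - ai * bj / nn) / ((ai + bj) / 2 - ai * bj / nn)
}
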