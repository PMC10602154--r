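test_that("a planted correlated block is recovered exactly amid noise", {
  hits <- 0L
  for (s in 1:5) {
    set.seed(s)
    n <- 300; p <- 40; block <- 16:25
    X <- matrix(rnorm(n * p), n)
    f <- rnorm(n)
    X[, block] <- sqrt(0.9) * f + sqrt(0.1) * X[, block]
    am <- make_am(X)
    dom <- build_crds(am, make_peaks(p), r_threshold = 0.3, min_peaks = 3)
    called <- names(dom$membership)[!is.na(dom$membership)]
    if (nrow(dom$domains) == 1L &&
        setequal(called, sprintf("p%05d", block))) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("independent peaks yield no CRDs", {
  zero <- 0L
  for (s in 1:5) {
    set.seed(100 + s)
    am <- make_am(matrix(rnorm(300 * 60), 300))
    dom <- build_crds(am, make_peaks(60), r_threshold = 0.3, min_peaks = 3)
    if (nrow(dom$domains) == 0L) zero <- zero + 1L
  }
  expect_gte(zero, 4L)
})

test_that("small instances equal the brute-force oracle exactly", {
  for (s in 1:25) {
    set.seed(1000 + s)
    p <- sample(4:8, 1)
    n <- 40
    X <- matrix(rnorm(n * p), n)
    if (runif(1) < 0.6) {
      lo <- sample(1:(p - 2), 1)
      blk <- lo:min(p, lo + sample(2:4, 1))
      f <- rnorm(n)
      X[, blk] <- sqrt(0.8) * f + sqrt(0.2) * X[, blk]
    }
    am <- make_am(X)
    dom <- suppressWarnings(build_crds(am, make_peaks(p), 0.3, 3))
    got <- lapply(seq_len(nrow(dom$domains)), function(i) {
      idx <- which(!is.na(dom$membership) &
                     dom$membership == dom$domains$crd_id[i])
      c(lo = min(idx), hi = max(idx))
    })
    C <- cor(X)
    want <- oracle_crd_calls(C, 0.3, 3)
    expect_identical(lapply(got, as.integer), lapply(want, as.integer))
    # every call is one of the exhaustively enumerated valid segments
    valid <- oracle_valid_segments(C, 0.3, 3)
    for (gseg in got) {
      expect_true(any(vapply(valid, function(v) all(v == gseg), TRUE)))
    }
  }
})

test_that("calls are invariant to sample order and affine peak rescaling", {
  set.seed(3)
  n <- 200; p <- 30
  X <- matrix(rnorm(n * p), n)
  f <- rnorm(n)
  X[, 11:18] <- sqrt(0.8) * f + sqrt(0.2) * X[, 11:18]
  peaks <- make_peaks(p)
  base <- build_crds(make_am(X), peaks)
  perm <- sample(n)
  Xp <- X[perm, ]
  rownames(Xp) <- sprintf("S%04d", seq_len(n))
  expect_identical(build_crds(make_am(Xp), peaks)$membership, base$membership)
  Xa <- sweep(sweep(X, 2, runif(p, 0.5, 3), `*`), 2, rnorm(p), `+`)
  expect_identical(build_crds(make_am(Xa), peaks)$membership, base$membership)
})

test_that("chromosomes below min_peaks are skipped with a notice", {
  set.seed(8)
  peaks <- new_peak_set(data.frame(
    chrom = c(rep("chr1", 10), "chr2", "chr2"),
    start = c(seq(0, 1800, by = 200), 0, 200),
    end = c(seq(0, 1800, by = 200), 0, 200) + 100,
    peak_id = sprintf("p%05d", 1:12)))
  am <- make_am(matrix(rnorm(100 * 12), 100))
  expect_message(build_crds(am, peaks, min_peaks = 3), "skipping chr2")
})

test_that("domain summaries report size, span and coverage", {
  x <- make_null_domains(50, 2, 5, seed = 2)
  x$d$domains$n_peaks <- c(5L, 7L)
  x$d$domains$start <- c(100L, 500L)
  x$d$domains$end <- c(27800L, 1000L)
  s <- crd_summaries(x$d)
  expect_equal(s$mean_peaks_per_crd, 6)
  expect_equal(s$median_length_bp, (27700 + 500) / 2)
  one <- x$d
  one$domains <- one$domains[1, ]
  expect_equal(crd_summaries(one)$median_length_bp, 27700)
  empty <- x$d
  empty$domains <- empty$domains[0, ]
  expect_error(crd_summaries(empty), "nonempty")
})

test_that("inside/outside GLM equals the 2x2 cross-product on binary |t|", {
  # 40 inside / 60 outside; |t| binary: inside 30 high 10 low, outside 15/45
  inside <- c(rep(TRUE, 40), rep(FALSE, 60))
  abs_t <- c(rep(1, 30), rep(0, 10), rep(1, 15), rep(0, 45))
  d <- structure(data.frame(peak_id = sprintf("p%05d", 1:100),
                            log2fc = 1, t_stat = abs_t,
                            p = 0.5, fdr = 0.5, direction = "up"),
                 class = c("DifferentialResult", "data.frame"))
  memb <- setNames(ifelse(inside, "CRD0001", NA_character_), d$peak_id)
  dom <- structure(list(domains = data.frame(crd_id = "CRD0001"),
                        membership = memb, signal = NULL),
                   class = "DomainSet")
  res <- inside_outside_glm(d, dom)
  expect_equal(res$odds_ratio, (30 * 45) / (10 * 15), tolerance = 1e-6)
  expect_lt(res$p, 0.01)
})

test_that("inside/outside GLM is null-calibrated and detects planted layout", {
  cover <- 0L
  for (s in 1:5) {
    set.seed(s)
    d <- structure(data.frame(peak_id = sprintf("p%05d", 1:500),
                              log2fc = 0, t_stat = rnorm(500), p = 0.5,
                              fdr = 0.5, direction = "up"),
                   class = c("DifferentialResult", "data.frame"))
    memb <- setNames(ifelse(seq_len(500) <= 200, "CRD0001", NA), d$peak_id)
    dom <- structure(list(domains = NULL, membership = memb, signal = NULL),
                     class = "DomainSet")
    res <- inside_outside_glm(d, dom)
    ci <- exp(log(res$odds_ratio) + c(-1.96, 1.96) * res$se_log_or)
    if (ci[1] <= 1 && ci[2] >= 1) cover <- cover + 1L
  }
  expect_gte(cover, 4L)
  # planted: large |t| only inside
  set.seed(77)
  tstat <- c(abs(rnorm(200, 2)), rnorm(300, 0, 0.5))
  d <- structure(data.frame(peak_id = sprintf("p%05d", 1:500), log2fc = 0,
                            t_stat = tstat, p = 0.5, fdr = 0.5,
                            direction = "up"),
                 class = c("DifferentialResult", "data.frame"))
  memb <- setNames(ifelse(seq_len(500) <= 200, "CRD0001", NA), d$peak_id)
  dom <- structure(list(domains = NULL, membership = memb, signal = NULL),
                   class = "DomainSet")
  res <- inside_outside_glm(d, dom)
  expect_gt(res$odds_ratio, 1)
  expect_lt(res$p, 0.01)
})

test_that("two-stage test is calibrated under the null and sensitive to shifts", {
  disc <- 0L; tot <- 0L
  for (s in 1:5) {
    x <- make_null_domains(100, 300, 5, seed = s)
    cd <- two_stage_crd_test(x$d, x$m)
    disc <- disc + sum(cd$significant); tot <- tot + nrow(cd)
  }
  expect_lte(disc / 5, 300 * 0.05)  # far fewer discoveries than alpha * m
  x <- make_null_domains(300, 100, 5, delta = 0.8, n_sig = 20, seed = 7)
  cd <- two_stage_crd_test(x$d, x$m)
  expect_gte(mean(cd$significant[1:20]), 0.9)
  expect_equal(unique(cd$direction[1:20][cd$significant[1:20]]), "up")
})

test_that("a single screened CRD reduces to a plain t test on its mean", {
  x <- make_null_domains(60, 1, 5, delta = 1.5, n_sig = 1, seed = 5)
  cd <- two_stage_crd_test(x$d, x$m, alpha = 0.05)
  g <- x$m$metadata$diagnosis
  tt <- t.test(x$d$signal[g == "case", 1], x$d$signal[g == "control", 1],
               var.equal = TRUE)
  expect_equal(cd$confirmation_p, tt$p.value, tolerance = 1e-12)
  expect_equal(cd$confirmation_p_adj, tt$p.value, tolerance = 1e-12)
  expect_true(cd$significant)
  expect_error(two_stage_crd_test(x$d, x$m, alpha = 1.2), "alpha")
})
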