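# 1-D severity gradient with signature peaks loading on it.
make_gradient <- function(n = 120, p = 60, noise = 0.5, seed = 1) {
  set.seed(seed)
  sev <- sort(rnorm(n))
  vals <- outer(sev, runif(p, 0.8, 1.2)) + matrix(rnorm(n * p, 0, noise), n)
  list(am = make_am(vals), severity = sev)
}

test_that("the leading diffusion component tracks a planted gradient", {
  x <- make_gradient(seed = 2)
  emb <- embed_samples(x$am, colnames(x$am$values), n_neighbors = 10, d = 5)
  rho <- abs(cor(emb$coordinates[, 1], x$severity, method = "spearman"))
  expect_gte(rho, 0.9)
})

test_that("duplicate samples embed at identical coordinates", {
  set.seed(3)
  vals <- matrix(rnorm(30 * 20), 30)
  vals[2, ] <- vals[1, ]
  emb <- embed_samples(make_am(vals), sprintf("p%05d", 1:20),
                       n_neighbors = 5, d = 4)
  expect_equal(emb$coordinates[1, ], emb$coordinates[2, ], tolerance = 1e-8)
})

test_that("a disconnected neighbour graph is reported with advice", {
  set.seed(4)
  vals <- rbind(matrix(rnorm(20 * 5), 20), matrix(rnorm(20 * 5, 100), 20))
  expect_error(embed_samples(make_am(vals), sprintf("p%05d", 1:5),
                             n_neighbors = 3, d = 3),
               "n_neighbors")
})

test_that("pseudotime is zero at the root and matches the dense oracle", {
  for (s in 1:5) {
    set.seed(3000 + s)
    n <- sample(7:10, 1)
    X <- matrix(rnorm(n * 4), n,
                dimnames = list(sprintf("S%02d", 1:n), paste0("p", 1:4)))
    emb <- embed_samples(make_am(X), paste0("p", 1:4), n_neighbors = 3, d = 6)
    root <- sample(rownames(X), 1)
    pt <- diffusion_pseudotime(emb, root = root)
    expect_equal(unname(pt[root]), 0)
    expect_equal(as.numeric(pt), oracle_dpt(X, which(rownames(X) == root), 3, 6),
                 tolerance = 1e-8)
  }
})

test_that("pseudotime is monotone along a chain of equally spaced samples", {
  n <- 12
  X <- cbind(seq_len(n) * 1.0, rep(0, n))
  rownames(X) <- sprintf("S%02d", 1:n); colnames(X) <- c("p1", "p2")
  emb <- embed_samples(make_am(X), "p1", n_neighbors = 2, d = 5)
  pt <- diffusion_pseudotime(emb, root = "S01")
  expect_true(all(diff(unname(pt)) > 0))
})

test_that("root defaults to the least-perturbed control and errors off-graph", {
  x <- make_gradient(seed = 5)
  x$am$metadata$diagnosis <- factor(
    ifelse(seq_len(120) > 60, "case", "control"), c("control", "case"))
  emb <- embed_samples(x$am, colnames(x$am$values), n_neighbors = 10, d = 5)
  pt <- diffusion_pseudotime(emb)
  ctrl <- rownames(x$am$values)[1:60]
  expect_equal(attr(pt, "root"),
               ctrl[which.min(emb$mean_signature[1:60])])
  expect_error(diffusion_pseudotime(emb, root = "nope"), "root")
})

test_that("staging recovers separated clusters and is seed-deterministic", {
  set.seed(6)
  centers <- c(0, 6, 12)
  sev <- rep(centers, each = 40) + rnorm(120, 0, 0.4)
  vals <- outer(sev, rep(1, 30)) + matrix(rnorm(120 * 30, 0, 0.4), 120)
  am <- make_am(vals)
  # n_neighbors larger than a cluster so the graph spans the gaps
  emb <- embed_samples(am, colnames(am$values), n_neighbors = 45, d = 5)
  pt <- diffusion_pseudotime(emb, root = rownames(vals)[1])
  st <- stage_samples(emb, resolution = 1, seed = 11, pseudotime = pt)
  expect_equal(ari(st, rep(1:3, each = 40)), 1)
  # stages ordered along pseudotime
  expect_true(all(diff(tapply(pt, st, mean)) > 0))
  st2 <- stage_samples(emb, resolution = 1, seed = 11, pseudotime = pt)
  expect_identical(st, st2)
})

test_that("vanishing resolution collapses to a single community with warning", {
  x <- make_gradient(n = 60, seed = 7)
  emb <- embed_samples(x$am, colnames(x$am$values), n_neighbors = 8, d = 4)
  expect_warning(st <- stage_samples(emb, resolution = 1e-4, seed = 1),
                 "single community")
  expect_equal(unique(unname(st)), 1L)
})

test_that("the pipeline is equivariant to sample permutation and affine rescaling", {
  x <- make_gradient(n = 80, seed = 8)
  sig <- colnames(x$am$values)
  emb <- embed_samples(x$am, sig, n_neighbors = 8, d = 4)
  pt <- diffusion_pseudotime(emb, root = rownames(x$am$values)[1])
  # per-peak affine rescaling is erased by the z-scoring
  vals2 <- sweep(sweep(x$am$values, 2, runif(60, 0.5, 2), `*`),
                 2, rnorm(60), `+`)
  emb2 <- embed_samples(make_am(vals2), sig, n_neighbors = 8, d = 4)
  pt2 <- diffusion_pseudotime(emb2, root = rownames(x$am$values)[1])
  expect_equal(as.numeric(pt), as.numeric(pt2), tolerance = 1e-8)
  # permuting samples permutes pseudotime
  set.seed(9); perm <- sample(80)
  vals3 <- x$am$values[perm, ]
  rownames(vals3) <- sprintf("S%04d", 1:80)
  emb3 <- embed_samples(make_am(vals3), sig, n_neighbors = 8, d = 4)
  root3 <- sprintf("S%04d", which(perm == 1))
  pt3 <- diffusion_pseudotime(emb3, root = root3)
  expect_equal(as.numeric(pt3[order(perm)]), as.numeric(pt), tolerance = 1e-8)
})

test_that("stage and pseudotime associations recover planted structure", {
  set.seed(10)
  n <- 200
  sev <- rnorm(n)
  prs <- 0.5 * sev + sqrt(0.75) * rnorm(n)
  case <- runif(n) < stats::plogis(1.5 * sev)
  vals <- outer(sev, rep(1, 80)) + matrix(rnorm(n * 80, 0, 0.7), n)
  am <- make_am(vals, diagnosis = ifelse(case, "case", "control"),
                extra = data.frame(age = runif(n, 30, 80),
                                   sex = factor(sample(c("M", "F"), n, TRUE)),
                                   prs = prs))
  st <- disease_stage(am, colnames(am$values), n_neighbors = 12, d = 5, seed = 3)
  a <- stage_associations(st, am$metadata)
  expect_gt(a$or_pseudotime$odds_ratio, 1)
  expect_lt(a$or_pseudotime$p, 0.05)
  expect_gt(a$stage_prs$beta, 0)
  expect_lt(a$stage_prs$p, 0.05)
  expect_gt(a$spearman_prs$rho, 0)
  # shuffled diagnosis: the pseudotime OR interval covers 1
  am2 <- am
  set.seed(11)
  am2$metadata$diagnosis <- sample(am$metadata$diagnosis)
  a2 <- stage_associations(disease_stage(am2, colnames(am2$values), n_neighbors = 12,
                                         d = 5, seed = 3), am2$metadata)
  expect_lte(a2$or_pseudotime$ci_low, 1)
  expect_gte(a2$or_pseudotime$ci_high, 1)
})

test_that("PRS-free metadata skips PRS analyses; flat stages are an error", {
  x <- make_gradient(n = 60, seed = 12)
  x$am$metadata$diagnosis <- factor(rep(c("control", "case"), 30),
                                    c("control", "case"))
  st <- disease_stage(x$am, colnames(x$am$values), n_neighbors = 8, d = 4)
  expect_message(a <- stage_associations(st, x$am$metadata), "skipped")
  expect_null(a$stage_prs)
  st_flat <- st
  st_flat$stage[] <- 1L
  meta <- x$am$metadata
  meta$prs <- rnorm(60); meta$age <- runif(60, 30, 70)
  meta$sex <- factor(rep(c("M", "F"), 30))
  expect_error(stage_associations(st_flat, meta), "no stage variance")
})
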