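#' Diffusion-map embedding of samples on a peak signature
#'
#' Restricts the matrix to the signature peaks, z-scores each peak, builds
#' a symmetric k-nearest-neighbour graph on Euclidean distances, converts
#' it to an adaptive-Gaussian-kernel affinity (bandwidth = each sample's
#' distance to its k-th neighbour), row-normalizes into a transition
#' operator and returns the top `d` nontrivial right eigenvectors scaled
#' by their eigenvalues -- the diffusion components on which staging and
#' pseudotime operate.
#'
#' @param m An `AccessibilityMatrix`.
#' @param signature Nonempty character vector of peak IDs (e.g. the
#'   upregulated disease peaks).
#' @param n_neighbors Neighbours per sample (2 <= n_neighbors <
#'   n_samples).
#' @param d Number of diffusion components to keep.
#' @return A `DiffusionEmbedding`: `coordinates` (n x d, eigenvalue
#'   scaled), `psi` (unscaled eigenvectors), `evals`, `affinity` (the
#'   kernel matrix), `mean_signature`, `diagnosis` (when present).
#' @export
embed_samples <- function(m, signature, n_neighbors = 15L, d = 10L) {
  stopifnot(inherits(m, "AccessibilityMatrix"), length(signature) >= 1L)
  if (n_neighbors < 2L || n_neighbors >= nrow(m$values)) {
    stop("need n_samples > n_neighbors >= 2", call. = FALSE)
  }
  X <- m$values[, signature, drop = FALSE]
  sds <- apply(X, 2L, sd)
  X <- scale(X[, sds > 0, drop = FALSE])
  if (ncol(X) == 0L) stop("signature peaks are all constant", call. = FALSE)
  n <- nrow(X)
  D <- as.matrix(dist(X))
  # tie-inclusive kNN: every point at or below the k-th neighbour distance
  # is a neighbour, so duplicated samples get identical neighbourhoods
  adj <- matrix(FALSE, n, n)
  sigma <- numeric(n)
  for (i in seq_len(n)) {
    d_i <- D[i, -i]
    kth <- sort(d_i, partial = n_neighbors)[n_neighbors]
    sigma[i] <- kth
    adj[i, ] <- D[i, ] <= kth
  }
  diag(adj) <- FALSE
  sigma[sigma == 0] <- min(sigma[sigma > 0], 1e-8)
  adj <- adj | t(adj)
  W <- exp(-D^2 / outer(sigma, sigma))
  W[!adj] <- 0
  diag(W) <- 0
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    W > 0, mode = "undirected"))
  if (comp$no > 1L) {
    stop("kNN graph is disconnected; increase n_neighbors", call. = FALSE)
  }
  eig <- transition_eigen(W)
  d <- min(d, n - 1L)
  take <- 2:(d + 1L)
  psi <- eig$psi[, take, drop = FALSE]
  evals <- eig$values[take]
  coords <- sweep(psi, 2L, evals, `*`)
  rownames(coords) <- rownames(psi) <- rownames(m$values)
  structure(list(
    coordinates = coords, psi = psi, evals = evals, affinity = W,
    mean_signature = rowMeans(m$values[, signature, drop = FALSE]),
    diagnosis = m$metadata$diagnosis
  ), class = "DiffusionEmbedding")
}

# Eigen system of the row-normalized transition operator P = D^-1 W via
# the conjugate symmetric matrix; right eigenvectors of P, deterministic
# sign (largest-magnitude entry positive).
transition_eigen <- function(W) {
  deg <- rowSums(W)
  s <- 1 / sqrt(deg)
  S <- W * outer(s, s)
  eig <- eigen(S, symmetric = TRUE)
  psi <- eig$vectors * s
  for (j in seq_len(ncol(psi))) {
    k <- which.max(abs(psi[, j]))
    if (psi[k, j] < 0) psi[, j] <- -psi[, j]
  }
  list(values = eig$values, psi = psi)
}

#' Diffusion pseudotime from a root sample
#'
#' Distance from the root in the diffusion-component space with each
#' component normalized to unit length and weighted by
#' lambda/(1 - lambda) -- the diffusion-pseudotime metric. The root
#' defaults to the control sample with the lowest mean
#' signature accessibility (the least-perturbed pole), and pseudotime is
#' min-max scaled to \[0, 1\] for reporting (root at 0).
#'
#' @param embedding A `DiffusionEmbedding`.
#' @param root Optional sample ID; default as above.
#' @return Named numeric vector of pseudotime in \[0, 1\], with
#'   attributes `root` and `raw` (unscaled distances).
#' @export
diffusion_pseudotime <- function(embedding, root = NULL) {
  stopifnot(inherits(embedding, "DiffusionEmbedding"))
  ids <- rownames(embedding$psi)
  if (is.null(root)) {
    cand <- if (!is.null(embedding$diagnosis)) {
      which(embedding$diagnosis == "control")
    } else seq_along(ids)
    root <- ids[cand[which.min(embedding$mean_signature[cand])]]
  }
  if (!root %in% ids) stop("root sample not in the graph", call. = FALSE)
  lam <- embedding$evals
  ok <- lam < 1 - 1e-12 & lam > 0
  psi <- embedding$psi[, ok, drop = FALSE]
  psi <- sweep(psi, 2L, sqrt(colSums(psi^2)), `/`)
  U <- sweep(psi, 2L, lam[ok] / (1 - lam[ok]), `*`)
  delta <- sweep(U, 2L, U[root, ], `-`)
  raw <- sqrt(rowSums(delta^2))
  pt <- if (max(raw) > 0) raw / max(raw) else raw
  names(pt) <- ids
  attr(pt, "root") <- root
  attr(pt, "raw") <- raw
  pt
}

#' Stage samples by community detection on the diffusion graph
#'
#' Leiden community detection (modularity objective) on the affinity
#' graph, with communities relabeled 1..K by ascending mean pseudotime so
#' stage 1 is the least-perturbed pole. A single detected community
#' yields a warning and all-1 stages.
#'
#' @param embedding A `DiffusionEmbedding`.
#' @param resolution Leiden resolution parameter.
#' @param seed RNG seed (community detection is stochastic).
#' @param pseudotime Optional pseudotime used for ordering; defaults to
#'   [diffusion_pseudotime()] with the default root.
#' @return Named integer vector of ordinal stages.
#' @export
stage_samples <- function(embedding, resolution = 1, seed = 1L,
                          pseudotime = NULL) {
  stopifnot(inherits(embedding, "DiffusionEmbedding"))
  if (is.null(pseudotime)) pseudotime <- diffusion_pseudotime(embedding)
  g <- igraph::graph_from_adjacency_matrix(embedding$affinity,
                                           mode = "undirected",
                                           weighted = TRUE)
  memb <- with_stream(seed, "leiden", {
    igraph::membership(igraph::cluster_leiden(
      g, objective_function = "modularity",
      resolution = resolution, n_iterations = 10L))
  })
  k <- length(unique(memb))
  if (k == 1L) {
    warning("single community detected; staging skipped")
    return(setNames(rep(1L, length(memb)), rownames(embedding$psi)))
  }
  mean_pt <- tapply(pseudotime, memb, mean)
  relab <- setNames(rank(mean_pt, ties.method = "first"), names(mean_pt))
  setNames(as.integer(relab[as.character(memb)]), rownames(embedding$psi))
}

#' One-call disease staging of a sample cohort
#'
#' Convenience wrapper: embed on the signature, compute diffusion
#' pseudotime from the root, stage by Leiden communities ordered along
#' pseudotime.
#'
#' @inheritParams embed_samples
#' @inheritParams stage_samples
#' @param root Optional root sample ID (see [diffusion_pseudotime()]).
#' @return A `StageResult`: `coordinates`, `stage`, `pseudotime`,
#'   `root_sample_id`, `embedding`.
#' @export
disease_stage <- function(m, signature, n_neighbors = 15L, d = 10L,
                          resolution = 1, root = NULL, seed = 1L) {
  emb <- embed_samples(m, signature, n_neighbors, d)
  pt <- diffusion_pseudotime(emb, root)
  st <- stage_samples(emb, resolution, seed, pt)
  structure(list(
    coordinates = emb$coordinates, stage = st, pseudotime = pt,
    root_sample_id = attr(pt, "root"), embedding = emb
  ), class = "StageResult")
}

#' @export
print.StageResult <- function(x, ...) {
  cat("StageResult:", length(x$pseudotime), "samples,",
      length(unique(x$stage)), "stages; root:", x$root_sample_id, "\n")
  print(table(stage = x$stage))
  invisible(x)
}

#' Associations of stage and pseudotime with diagnosis and PRS
#'
#' Three analyses: (i) logistic regression of case status on standardized
#' pseudotime (odds ratio per SD); (ii) the linear model
#' `stage ~ PRS + Age + Age^2 + Sex` (PRS coefficient and p); (iii)
#' Spearman correlation of pseudotime with PRS. The PRS analyses are
#' skipped with a notice when the metadata has no `prs` column.
#'
#' @param s A `StageResult`.
#' @param meta Sample metadata (with `diagnosis`, `age`, `sex`, optional
#'   `prs`), rows aligned to the staged samples by `sample_id`.
#' @return List of class `StageAssociations`: `or_pseudotime` (list:
#'   odds_ratio, p, ci_low, ci_high), `stage_prs` (list: beta, p, n) or
#'   NULL, `spearman_prs` (list: rho, p) or NULL.
#' @export
stage_associations <- function(s, meta) {
  stopifnot(inherits(s, "StageResult"))
  meta <- meta[match(names(s$pseudotime), meta$sample_id), , drop = FALSE]
  case <- as.integer(meta$diagnosis == "case")
  pt_sd <- as.numeric(scale(s$pseudotime))
  fit <- glm(case ~ pt_sd, family = binomial())
  est <- summary(fit)$coefficients["pt_sd", ]
  or <- list(odds_ratio = unname(exp(est["Estimate"])),
             p = unname(est["Pr(>|z|)"]),
             ci_low = unname(exp(est["Estimate"] - 1.96 * est["Std. Error"])),
             ci_high = unname(exp(est["Estimate"] + 1.96 * est["Std. Error"])))
  stage_prs <- spearman_prs <- NULL
  if (!is.null(meta$prs)) {
    if (length(unique(s$stage)) < 2L) {
      stop("no stage variance: stage model is undefined", call. = FALSE)
    }
    dat <- data.frame(stage = as.numeric(s$stage), prs = meta$prs,
                      age = meta$age, sex = meta$sex)
    lmfit <- lm(stage ~ prs + age + I(age^2) + sex, data = dat)
    co <- summary(lmfit)$coefficients["prs", ]
    stage_prs <- list(beta = unname(co["Estimate"]),
                      p = unname(co["Pr(>|t|)"]), n = nrow(dat))
    ct <- suppressWarnings(cor.test(s$pseudotime, meta$prs,
                                    method = "spearman", exact = FALSE))
    spearman_prs <- list(rho = unname(ct$estimate), p = ct$p.value)
  } else {
    message("metadata has no `prs` column: PRS analyses skipped")
  }
  structure(list(or_pseudotime = or, stage_prs = stage_prs,
                 spearman_prs = spearman_prs),
            class = "StageAssociations")
}

#' @export
print.StageAssociations <- function(x, ...) {
  cat(sprintf("case ~ pseudotime: OR/SD = %.3f (p = %.3g)\n",
              x$or_pseudotime$odds_ratio, x$or_pseudotime$p))
  if (!is.null(x$stage_prs)) {
    cat(sprintf("stage ~ PRS + Age + Age^2 + Sex: beta = %.3f (p = %.3g, n = %d)\n",
                x$stage_prs$beta, x$stage_prs$p, x$stage_prs$n))
    cat(sprintf("Spearman(pseudotime, PRS): rho = %.3f (p = %.3g)\n",
                x$spearman_prs$rho, x$spearman_prs$p))
  }
  invisible(x)
}
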