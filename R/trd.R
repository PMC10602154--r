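#' Goodman-Kruskal (Baker-Hubert) Gamma for a clustering
#'
#' Concordance between pairwise distances and cluster co-membership: over
#' all comparisons of a within-cluster distance w with a between-cluster
#' distance b, Gamma = (s+ - s-)/(s+ + s-), where s+ counts b > w
#' (concordant) and s- counts b < w (discordant); exact ties contribute to
#' neither. Gamma is 1 when every between-cluster distance exceeds every
#' within-cluster distance.
#'
#' @param dist A `dist` object or condensed distance vector over n items.
#' @param labels Cluster labels of the n items (>= 2 clusters, at least
#'   two within-pairs and two between-pairs).
#' @return Gamma in \[-1, 1\].
#' @export
gamma_statistic <- function(dist, labels) {
  dv <- as.numeric(dist)
  n <- as.integer((1 + sqrt(1 + 8 * length(dv))) / 2)
  if (length(labels) != n) {
    stop("labels length does not match the distance object", call. = FALSE)
  }
  if (length(unique(labels)) < 2L) {
    stop("Gamma is undefined for a single cluster", call. = FALSE)
  }
  pair_i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  pair_j <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n))
  same <- labels[pair_i] == labels[pair_j]
  w <- dv[same]; b <- dv[!same]
  if (length(w) < 2L || length(b) < 2L) {
    stop("Gamma needs at least two within-pairs and two between-pairs",
         call. = FALSE)
  }
  sw <- sort(w)
  # for each between distance: #within strictly below / strictly above
  n_less <- findInterval(b, sw, left.open = TRUE)        # sw[k] <  b
  n_leq <- findInterval(b, sw)                           # sw[k] <= b
  s_plus <- sum(n_less)
  s_minus <- sum(length(w) - n_leq)
  if (s_plus + s_minus == 0) return(0)
  (s_plus - s_minus) / (s_plus + s_minus)
}

# Average-linkage clustering of domain signals with Gamma-selected k.
# Core used by build_trds; exposed to make signal-level simulation direct.
trd_cluster <- function(signal, k_range, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  keep <- apply(signal, 2L, function(x) sd(x) > 0)
  if (any(!keep)) {
    warning(sprintf("dropping %d CRD(s) with constant signal", sum(!keep)))
    signal <- signal[, keep, drop = FALSE]
  }
  n <- ncol(signal)
  if (n < 3L) stop("need at least 3 CRDs with non-constant signal", call. = FALSE)
  dmat <- as.dist(1 - cor(signal))
  tree <- hclust(dmat, method = linkage)
  k_range <- sort(unique(as.integer(k_range)))
  k_range <- k_range[k_range >= 2L & k_range <= n - 1L]
  if (!length(k_range)) stop("k_range is empty after clipping to [2, n-1]",
                             call. = FALSE)
  gamma_trace <- vapply(k_range, function(k) {
    # cuts leaving fewer than two within- or between-pairs have no Gamma
    tryCatch(gamma_statistic(dmat, cutree(tree, k = k)),
             error = function(e) NA_real_)
  }, 0)
  names(gamma_trace) <- k_range
  if (all(is.na(gamma_trace))) {
    stop("Gamma is undefined at every candidate k", call. = FALSE)
  }
  best_k <- k_range[which.max(gamma_trace)]   # NAs never win; ties: smallest k
  raw <- cutree(tree, k = best_k)
  # deterministic relabeling: TRD 1 = largest cluster (first CRD on ties)
  sizes <- table(raw)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relab <- setNames(seq_along(ord), names(sizes)[ord])
  labels <- setNames(unname(relab[as.character(raw)]), colnames(signal))
  list(labels = labels, k = best_k, gamma_trace = gamma_trace, tree = tree)
}

#' Discover trans-regulatory domains (TRDs) among differential CRDs
#'
#' Takes the significant ("disease") CRDs from the two-stage test,
#' computes the correlation of their per-sample mean signals across all
#' samples, and clusters the distance 1 - r by average-linkage (complete
#' linkage by flag) hierarchical clustering. For every candidate k the
#' tree is cut and the Goodman-Kruskal Gamma computed; the returned
#' partition is at the Gamma-maximizing k (smallest k on ties). TRDs are
#' renumbered by decreasing size.
#'
#' @param crd_diff A `CrdDifferential` from [two_stage_crd_test()].
#' @param d The `DomainSet`.
#' @param m The `AccessibilityMatrix` (unused beyond dimension checks;
#'   signals live in `d`).
#' @param k_range Candidate cluster counts (clipped to \[2, n_CRDs - 1\]).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return A `TrdPartition`: `labels` (crd_id -> TRD integer), `k`,
#'   `gamma_trace` (named by k), `tree` (the hclust record).
#' @export
build_trds <- function(crd_diff, d, m = NULL, k_range = 2:15,
                       linkage = c("average", "complete")) {
  stopifnot(inherits(crd_diff, "CrdDifferential"), inherits(d, "DomainSet"))
  sig_ids <- crd_diff$crd_id[crd_diff$significant]
  if (length(sig_ids) < 3L) {
    stop("need at least 3 significant CRDs to build TRDs", call. = FALSE)
  }
  cl <- trd_cluster(d$signal[, sig_ids, drop = FALSE], k_range,
                    match.arg(linkage))
  structure(cl, class = "TrdPartition")
}

#' @export
print.TrdPartition <- function(x, ...) {
  cat("TrdPartition:", length(x$labels), "CRDs in", x$k, "TRDs",
      sprintf("(Gamma = %.3f)\n", max(x$gamma_trace, na.rm = TRUE)))
  print(table(TRD = x$labels))
  invisible(x)
}

#' Up/down composition of each TRD
#'
#' Counts up- and down-regulated CRDs per TRD (directions from the
#' two-stage test) and flags TRDs whose up fraction exceeds
#' `up_threshold` as predominantly upregulated -- the signature of the
#' disease TRD.
#'
#' @param p A `TrdPartition`.
#' @param crd_diff The matching `CrdDifferential`.
#' @param up_threshold Up-fraction cutoff for the flag (default 0.75).
#' @return Data frame: `trd`, `n_crds`, `n_up`, `n_down`, `up_fraction`,
#'   `predominantly_up`.
#' @export
trd_direction_profile <- function(p, crd_diff, up_threshold = 0.75) {
  stopifnot(inherits(p, "TrdPartition"), inherits(crd_diff, "CrdDifferential"))
  dir <- setNames(crd_diff$direction, crd_diff$crd_id)[names(p$labels)]
  out <- do.call(rbind, lapply(sort(unique(p$labels)), function(t) {
    dd <- dir[p$labels == t]
    data.frame(trd = t, n_crds = length(dd),
               n_up = sum(dd == "up", na.rm = TRUE),
               n_down = sum(dd == "down", na.rm = TRUE))
  }))
  out$up_fraction <- out$n_up / out$n_crds
  out$predominantly_up <- out$up_fraction > up_threshold
  out
}

#' Rank correlation of two fold-change vectors over shared peaks
#'
#' Spearman correlation of two per-peak log2 fold-change vectors (e.g.
#' disease vs control against fetal vs adult) restricted to their shared
#' peak IDs; used to ask whether a TRD's disease upregulation tracks
#' developmental upregulation.
#'
#' @param set_a_log2fc,set_b_log2fc Named numeric vectors (names = peak
#'   IDs); at least 10 shared peaks required.
#' @return List with `rho`, `p`, `n`.
#' @export
fold_change_correlation <- function(set_a_log2fc, set_b_log2fc) {
  shared <- intersect(names(set_a_log2fc), names(set_b_log2fc))
  if (length(shared) < 10L) {
    stop("need at least 10 shared peaks", call. = FALSE)
  }
  ct <- suppressWarnings(
    cor.test(set_a_log2fc[shared], set_b_log2fc[shared],
             method = "spearman", exact = FALSE)
  )
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(shared))
}
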