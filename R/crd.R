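#' Assemble cis-regulatory domains (CRDs) from inter-individual correlation
#'
#' Per chromosome, an agglomerative binary tree is grown over the
#' genomically ordered peaks by repeatedly merging the adjacent pair of
#' clusters with the highest similarity, where similarity between two
#' clusters is the mean pairwise Pearson correlation of their cross
#' members (ties break to the leftmost pair). CRDs are the maximal
#' subtrees whose mean internal pairwise correlation is at least
#' `r_threshold` and whose size is at least `min_peaks`; remaining peaks
#' are reported outside any CRD. Because only genomically adjacent
#' clusters may merge, every CRD is a contiguous run of peaks -- the
#' defining cis property. The child-link condition (the two halves of a
#' qualifying subtree must themselves be linked at `r_threshold`)
#' prevents a tightly correlated block from absorbing flanking background
#' peaks while its internal mean is still above threshold.
#'
#' The calls are invariant to sample order and to per-peak affine
#' rescaling (anything preserving Pearson correlations).
#'
#' @param m An `AccessibilityMatrix` (>= 30 samples recommended for
#'   correlation stability; fewer triggers a warning).
#' @param peaks The matching `PeakSet`; matrix columns are aligned to it.
#' @param r_threshold Minimum mean internal correlation of a CRD.
#' @param min_peaks Minimum CRD size.
#' @return A `DomainSet`: `domains` (per-CRD table: crd_id, chrom,
#'   start, end, n_peaks, mean_internal_correlation), `membership` (named
#'   peak_id -> crd_id, NA outside), and `signal` (samples x CRDs matrix
#'   of mean member accessibility).
#' @export
build_crds <- function(m, peaks, r_threshold = 0.3, min_peaks = 3L) {
  stopifnot(inherits(m, "AccessibilityMatrix"), inherits(peaks, "PeakSet"))
  if (nrow(m$values) < 30L) {
    warning("fewer than 30 samples: inter-individual correlations are unstable")
  }
  miss <- setdiff(peaks$peak_id, colnames(m$values))
  if (length(miss)) stop("matrix lacks columns for some peaks", call. = FALSE)
  Y <- m$values[, peaks$peak_id, drop = FALSE]

  membership <- setNames(rep(NA_character_, nrow(peaks)), peaks$peak_id)
  dom_rows <- list()
  crd_counter <- 0L
  for (chr in unique(peaks$chrom)) {
    idx <- which(peaks$chrom == chr)
    if (length(idx) < min_peaks) {
      message(sprintf("skipping %s: fewer than min_peaks peaks", chr))
      next
    }
    C <- cor(Y[, idx, drop = FALSE])
    segs <- crd_tree_segments(C, r_threshold, min_peaks)
    for (s in segs) {
      crd_counter <- crd_counter + 1L
      ids <- peaks$peak_id[idx[s$lo:s$hi]]
      crd_id <- sprintf("CRD%04d", crd_counter)
      membership[ids] <- crd_id
      dom_rows[[crd_counter]] <- data.frame(
        crd_id = crd_id, chrom = chr,
        start = min(peaks$start[idx[s$lo:s$hi]]),
        end = max(peaks$end[idx[s$lo:s$hi]]),
        n_peaks = s$hi - s$lo + 1L,
        mean_internal_correlation = s$mean_corr,
        stringsAsFactors = FALSE
      )
    }
  }
  domains <- if (length(dom_rows)) do.call(rbind, dom_rows) else
    data.frame(crd_id = character(0), chrom = character(0),
               start = integer(0), end = integer(0), n_peaks = integer(0),
               mean_internal_correlation = numeric(0))
  signal <- domain_signal(Y, membership, domains$crd_id)
  structure(list(domains = domains, membership = membership, signal = signal),
            class = "DomainSet")
}

# Greedy adjacency-constrained agglomeration on one chromosome's
# correlation matrix. A subtree qualifies as a CRD when its size reaches
# min_peaks, its mean internal pairwise correlation reaches r_threshold,
# AND the mean cross-correlation between its two child clusters (the
# merge similarity) reaches r_threshold -- the child-link condition stops
# a strong block from absorbing flanking background peaks while its
# internal mean is still above threshold. CRDs are the maximal
# qualifying subtrees.
crd_tree_segments <- function(C, r_threshold, min_peaks) {
  p <- nrow(C)
  # node bookkeeping: leaves 1..p, internal nodes appended as merges happen
  node_lo <- seq_len(p); node_hi <- seq_len(p)
  node_W <- rep(0, p)                    # sum of within-pair correlations
  node_link <- rep(NA_real_, p)          # merge similarity of the node's children
  node_child <- vector("list", p)
  cl_of <- seq_len(p)                    # active cluster slot per position, left to right
  M <- C                                 # cross-correlation sums between clusters
  size <- rep(1L, p)
  active_id <- seq_len(p)                # node id per matrix slot

  while (length(cl_of) > 1L) {
    k <- length(cl_of)
    a <- cl_of[seq_len(k - 1L)]
    b <- cl_of[2:k]
    sims <- M[cbind(a, b)] / (size[a] * size[b])
    j <- which.max(sims)                 # leftmost max
    sa <- cl_of[j]; sb <- cl_of[j + 1L]
    na <- active_id[sa]; nb <- active_id[sb]
    node_lo <- c(node_lo, node_lo[na]); node_hi <- c(node_hi, node_hi[nb])
    node_W <- c(node_W, node_W[na] + node_W[nb] + M[sa, sb])
    node_link <- c(node_link, sims[j])
    node_child <- c(node_child, list(c(na, nb)))
    new_id <- length(node_lo)
    # fold cluster sb into slot sa
    M[sa, ] <- M[sa, ] + M[sb, ]
    M[, sa] <- M[, sa] + M[, sb]
    size[sa] <- size[sa] + size[sb]
    active_id[sa] <- new_id
    cl_of <- cl_of[-(j + 1L)]
  }
  root <- active_id[cl_of[1L]]

  segs <- list()
  stack <- root
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    sz <- node_hi[nd] - node_lo[nd] + 1L
    mean_corr <- if (sz >= 2L) node_W[nd] / choose(sz, 2) else NA_real_
    if (sz >= max(2L, min_peaks) && mean_corr >= r_threshold &&
        node_link[nd] >= r_threshold) {
      segs[[length(segs) + 1L]] <- list(lo = node_lo[nd], hi = node_hi[nd],
                                        mean_corr = mean_corr)
    } else if (!is.null(node_child[[nd]])) {
      stack <- c(stack, node_child[[nd]])
    }
  }
  segs[order(vapply(segs, `[[`, 0L, "lo"))]
}

domain_signal <- function(Y, membership, crd_ids) {
  sig <- matrix(NA_real_, nrow(Y), length(crd_ids),
                dimnames = list(rownames(Y), crd_ids))
  for (cid in crd_ids) {
    sig[, cid] <- rowMeans(Y[, names(membership)[!is.na(membership) &
                                                   membership == cid],
                             drop = FALSE])
  }
  sig
}

#' @export
print.DomainSet <- function(x, ...) {
  cat("DomainSet:", nrow(x$domains), "CRDs covering",
      sum(!is.na(x$membership)), "of", length(x$membership), "peaks\n")
  invisible(x)
}

#' Summary statistics of a domain set
#'
#' @param d A nonempty `DomainSet`.
#' @return List with `n_crds`, `mean_peaks_per_crd`, `median_length_bp`,
#'   `fraction_peaks_inside`.
#' @export
crd_summaries <- function(d) {
  stopifnot(inherits(d, "DomainSet"))
  if (nrow(d$domains) == 0L) {
    stop("crd_summaries requires a nonempty DomainSet", call. = FALSE)
  }
  list(
    n_crds = nrow(d$domains),
    mean_peaks_per_crd = mean(d$domains$n_peaks),
    median_length_bp = median(d$domains$end - d$domains$start),
    fraction_peaks_inside = mean(!is.na(d$membership))
  )
}

#' Inside/outside-CRD enrichment of disease association
#'
#' Logistic regression of inside-CRD membership (0/1, per peak) on the
#' absolute disease t statistic: are disease-associated peaks more likely
#' to sit inside CRDs? Returns the odds ratio per unit |t| with its Wald
#' p value.
#'
#' @param diff A `DifferentialResult`.
#' @param d A `DomainSet` over the same peak universe.
#' @return List with `odds_ratio`, `p`, `se_log_or`, `n`.
#' @export
inside_outside_glm <- function(diff, d) {
  stopifnot(inherits(diff, "DifferentialResult"), inherits(d, "DomainSet"))
  inside <- as.integer(!is.na(d$membership[diff$peak_id]))
  if (all(inside == 1L) || all(inside == 0L)) {
    stop("all peaks on one side of the CRD boundary: model is separated",
         call. = FALSE)
  }
  fit <- glm(inside ~ abs_t, family = binomial(),
             data = data.frame(inside = inside, abs_t = abs(diff$t_stat)))
  est <- summary(fit)$coefficients["abs_t", ]
  list(odds_ratio = unname(exp(est["Estimate"])),
       p = unname(est["Pr(>|z|)"]),
       se_log_or = unname(est["Std. Error"]),
       n = length(inside))
}

#' Two-stage differential-CRD test
#'
#' Stage 1 (screening): for every CRD, a two-sample Hotelling T-squared
#' omnibus test of any member-peak group effect (exact F when the member
#' count permits, otherwise a t test on the domain mean); screening p
#' values are BH-adjusted across CRDs and CRDs passing `fdr < alpha` are
#' screened in. Stage 2 (confirmation): a pooled-variance t test on the
#' CRD mean signal, Bonferroni-corrected within the screened set. A CRD
#' is differential iff both stages pass; direction is the sign of the
#' domain-signal log2 fold change.
#'
#' @param d A `DomainSet`.
#' @param m The `AccessibilityMatrix` it was built from.
#' @param alpha FDR level of the procedure, in (0, 1).
#' @param group Metadata column with two levels.
#' @return A `CrdDifferential` data frame: `crd_id`, `log2fc`,
#'   `screening_p`, `screening_fdr`, `confirmation_p`,
#'   `confirmation_p_adj`, `significant`, `direction`.
#' @export
two_stage_crd_test <- function(d, m, alpha = 0.05, group = "diagnosis") {
  stopifnot(inherits(d, "DomainSet"), inherits(m, "AccessibilityMatrix"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("alpha must lie in (0, 1)", call. = FALSE)
  }
  g <- droplevels(factor(m$metadata[[group]]))
  stopifnot(nlevels(g) == 2L)
  i1 <- which(g == levels(g)[1L]); i2 <- which(g == levels(g)[2L])
  crd_ids <- d$domains$crd_id
  if (!length(crd_ids)) {
    return(structure(data.frame(crd_id = character(0), log2fc = numeric(0),
                                screening_p = numeric(0), screening_fdr = numeric(0),
                                confirmation_p = numeric(0),
                                confirmation_p_adj = numeric(0),
                                significant = logical(0), direction = character(0)),
                     class = c("CrdDifferential", "data.frame")))
  }
  screening_p <- vapply(crd_ids, function(cid) {
    members <- names(d$membership)[!is.na(d$membership) & d$membership == cid]
    Y <- m$values[, members, drop = FALSE]
    hotelling_two_sample_p(Y[i1, , drop = FALSE], Y[i2, , drop = FALSE])
  }, 0)
  screening_fdr <- bh_adjust(screening_p)
  screened <- screening_fdr < alpha

  mean_sig <- d$signal[, crd_ids, drop = FALSE]
  log2fc <- colMeans(mean_sig[i2, , drop = FALSE]) -
    colMeans(mean_sig[i1, , drop = FALSE])
  confirmation_p <- vapply(crd_ids, function(cid) {
    pooled_t_p(mean_sig[i1, cid], mean_sig[i2, cid])
  }, 0)
  n_screened <- sum(screened)
  confirmation_p_adj <- rep(NA_real_, length(crd_ids))
  if (n_screened > 0L) {
    confirmation_p_adj[screened] <- pmin(1, confirmation_p[screened] * n_screened)
  }
  significant <- screened & !is.na(confirmation_p_adj) &
    confirmation_p_adj < alpha
  structure(data.frame(
    crd_id = crd_ids, log2fc = unname(log2fc),
    screening_p = unname(screening_p), screening_fdr = unname(screening_fdr),
    confirmation_p = unname(confirmation_p),
    confirmation_p_adj = unname(confirmation_p_adj),
    significant = unname(significant),
    direction = ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", NA)),
    stringsAsFactors = FALSE
  ), class = c("CrdDifferential", "data.frame"), alpha = alpha)
}

#' @export
print.CrdDifferential <- function(x, ...) {
  cat("CrdDifferential:", nrow(x), "CRDs;", sum(x$significant),
      "differential at the two-stage FDR", attr(x, "alpha") %||% 0.05, "\n")
  invisible(x)
}

# Exact-F two-sample Hotelling T^2 p value; falls back to the pooled t on
# the row mean when the dimension is too high for the pooled covariance.
hotelling_two_sample_p <- function(Y1, Y2) {
  n1 <- nrow(Y1); n2 <- nrow(Y2); p <- ncol(Y1); n <- n1 + n2
  if (p == 1L || n - p - 1L <= 0L) {
    return(pooled_t_p(rowMeans(Y1), rowMeans(Y2)))
  }
  dbar <- colMeans(Y1) - colMeans(Y2)
  S <- ((n1 - 1) * stats::cov(Y1) + (n2 - 1) * stats::cov(Y2)) / (n - 2)
  Sd <- tryCatch(solve(S, dbar), error = function(e) {
    solve(S + diag(1e-8 * mean(diag(S)), p), dbar)
  })
  T2 <- (n1 * n2 / n) * sum(dbar * Sd)
  Fstat <- T2 * (n - p - 1) / ((n - 2) * p)
  pf(Fstat, p, n - p - 1, lower.tail = FALSE)
}

pooled_t_p <- function(x1, x2) {
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * var(x1) + (n2 - 1) * var(x2)) / (n1 + n2 - 2)
  if (sp2 == 0) return(1)
  tval <- (mean(x1) - mean(x2)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(tval), n1 + n2 - 2)
}
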