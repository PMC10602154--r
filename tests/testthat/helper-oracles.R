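# Independent brute-force oracles. Deliberately naive (double loops,
# exhaustive enumeration) and kept free of the package's internal code
# paths so they can catch implementation bugs.

# Mean pairwise correlation of a contiguous index segment, double loop.
oracle_segment_mean_corr <- function(C, lo, hi) {
  s <- 0; k <- 0
  for (i in lo:(hi - 1)) for (j in (i + 1):hi) {
    s <- s + C[i, j]; k <- k + 1
  }
  s / k
}

# Exhaustive enumeration of every valid contiguous segment under the CRD
# acceptance rule (size >= min_peaks, mean internal corr >= threshold).
oracle_valid_segments <- function(C, r_threshold, min_peaks) {
  p <- nrow(C)
  out <- list()
  for (lo in 1:p) for (hi in lo:p) {
    sz <- hi - lo + 1
    if (sz < max(2, min_peaks)) next
    if (oracle_segment_mean_corr(C, lo, hi) >= r_threshold) {
      out[[length(out) + 1]] <- c(lo = lo, hi = hi)
    }
  }
  out
}

# Naive re-derivation of the CRD calls: greedy adjacency-constrained
# agglomeration with double-loop cluster similarities (mean cross-pair
# correlation, leftmost maximum on ties), then top-down extraction of
# maximal subtrees passing the acceptance rule (mean internal corr and
# child-link similarity both >= threshold, size >= min_peaks).
oracle_crd_calls <- function(C, r_threshold, min_peaks) {
  p <- nrow(C)
  clusters <- lapply(1:p, function(i) i)
  nodes <- lapply(1:p, function(i) list(members = i, children = NULL, link = NA))
  ids <- 1:p
  cross_mean <- function(a, b) {
    s <- 0
    for (i in a) for (j in b) s <- s + C[i, j]
    s / (length(a) * length(b))
  }
  while (length(clusters) > 1) {
    best <- -Inf; bj <- 1
    for (j in 1:(length(clusters) - 1)) {
      sim <- cross_mean(clusters[[j]], clusters[[j + 1]])
      if (sim > best) { best <- sim; bj <- j }
    }
    newm <- c(clusters[[bj]], clusters[[bj + 1]])
    nodes[[length(nodes) + 1]] <- list(members = newm,
                                       children = c(ids[bj], ids[bj + 1]),
                                       link = best)
    clusters[[bj]] <- newm
    clusters[[bj + 1]] <- NULL
    ids[bj] <- length(nodes)
    ids <- ids[-(bj + 1)]
  }
  segs <- list()
  stack <- ids[1]
  while (length(stack)) {
    nd <- nodes[[stack[length(stack)]]]
    stack <- stack[-length(stack)]
    mem <- nd$members
    ok <- length(mem) >= max(2, min_peaks) &&
      oracle_segment_mean_corr(C, min(mem), max(mem)) >= r_threshold &&
      !is.na(nd$link) && nd$link >= r_threshold
    if (ok) {
      segs[[length(segs) + 1]] <- c(lo = min(mem), hi = max(mem))
    } else if (!is.null(nd$children)) {
      stack <- c(stack, nd$children)
    }
  }
  segs[order(vapply(segs, `[`, 0, "lo"))]
}

# Goodman-Kruskal Gamma by explicit double loop over all
# (within-pair, between-pair) comparisons; exact ties count for neither.
oracle_gamma <- function(dv, labels) {
  n <- length(labels)
  pi <- combn(n, 2)
  same <- labels[pi[1, ]] == labels[pi[2, ]]
  w <- dv[same]; b <- dv[!same]
  sp <- 0; sm <- 0
  for (wi in w) for (bi in b) {
    if (bi > wi) sp <- sp + 1 else if (bi < wi) sm <- sm + 1
  }
  (sp - sm) / (sp + sm)
}

# Dense diffusion-pseudotime oracle: rebuilds the kernel and transition
# operator entry by entry from the data, takes right eigenvectors of the
# non-symmetric P directly, unit-normalizes them, weights by
# lambda/(1-lambda) and measures the Euclidean distance to the root,
# min-max scaled. Matches the package path only if both are correct.
oracle_dpt <- function(X, root_idx, n_neighbors, d) {
  n <- nrow(X)
  Z <- scale(X[, apply(X, 2, sd) > 0, drop = FALSE])
  D <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) D[i, j] <- sqrt(sum((Z[i, ] - Z[j, ])^2))
  kn <- matrix(0L, n, n_neighbors)
  sigma <- numeric(n)
  for (i in 1:n) {
    ord <- order(D[i, ])[-1]
    kn[i, ] <- ord[1:n_neighbors]
    sigma[i] <- D[i, ord[n_neighbors]]
  }
  W <- matrix(0, n, n)
  for (i in 1:n) for (j in 1:n) {
    if (i != j && (j %in% kn[i, ] || i %in% kn[j, ])) {
      W[i, j] <- exp(-D[i, j]^2 / (sigma[i] * sigma[j]))
    }
  }
  P <- W / rowSums(W)
  eg <- eigen(P)
  lam <- Re(eg$values)
  V <- Re(eg$vectors)
  ord <- order(lam, decreasing = TRUE)
  lam <- lam[ord]; V <- V[, ord, drop = FALSE]
  take <- 2:min(d + 1, n)
  lam <- lam[take]; V <- V[, take, drop = FALSE]
  keep <- lam < 1 - 1e-12 & lam > 0
  lam <- lam[keep]; V <- V[, keep, drop = FALSE]
  V <- sweep(V, 2, sqrt(colSums(V^2)), `/`)
  U <- sweep(V, 2, lam / (1 - lam), `*`)
  raw <- sqrt(rowSums(sweep(U, 2, U[root_idx, ], `-`)^2))
  if (max(raw) > 0) raw / max(raw) else raw
}
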