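#' Per-cell enrichment z-scores of a peak set in single-cell ATAC
#'
#' For every cell, the observed fraction of its depth falling in the
#' target peaks is compared with `B` background peak sets matched to the
#' target on quantile bins of depth-normalized mean accessibility:
#' `z = (obs - mean_bg) / sd_bg`. Scores are invariant to scaling all of
#' a cell's counts (depth normalization) and average approximately zero
#' for random target sets. The default matching uses bins of roughly
#' five peaks (at least ten bins): coarser bins leave an
#' accessibility-mismatch bias in the per-cell z of a random target set.
#'
#' @param cells A `CellMatrix`.
#' @param target Character vector of peak IDs (warning below 10 peaks).
#' @param B Number of background draws (>= 20).
#' @param seed RNG seed for the background sampling.
#' @param n_bins Number of accessibility-matching quantile bins; default
#'   `max(10, min(100, floor(n_peaks / 5)))`.
#' @return An `EnrichmentScores` data frame: `cell_id`, `z`, `observed`;
#'   attributes `B` and `target_size`. Cells whose background sd is zero
#'   get z = 0 and are flagged in the `degenerate` column.
#' @export
cell_set_zscores <- function(cells, target, B = 50L, seed = 1L,
                             n_bins = NULL) {
  stopifnot(inherits(cells, "CellMatrix"))
  if (B < 20L) stop("B must be at least 20", call. = FALSE)
  peaks <- colnames(cells$counts)
  if (!all(target %in% peaks)) stop("target peaks outside the universe",
                                    call. = FALSE)
  if (length(target) < 10L) warning("target set smaller than 10 peaks")
  counts <- cells$counts
  depth <- Matrix::rowSums(counts)
  mean_acc <- Matrix::colSums(counts / depth) / nrow(counts)
  n_bins <- n_bins %||% max(10L, min(100L, floor(length(peaks) / 5)))
  bin <- cut(rank(mean_acc, ties.method = "first"),
             breaks = n_bins, labels = FALSE)
  names(bin) <- peaks
  by_bin <- split(peaks, bin)

  t_idx <- match(target, peaks)
  obs <- as.numeric(counts[, t_idx, drop = FALSE] %*%
                      rep(1, length(t_idx))) / depth
  bg <- with_stream(seed, "background", {
    tb <- bin[target]
    sapply(seq_len(B), function(b) {
      draw <- vapply(tb, function(bb) {
        pool <- by_bin[[as.character(bb)]]
        pool[sample.int(length(pool), 1L)]
      }, "")
      idx <- match(draw, peaks)
      as.numeric(counts[, idx, drop = FALSE] %*% rep(1, length(idx))) / depth
    })
  })
  mu <- rowMeans(bg)
  sdev <- apply(bg, 1L, sd)
  degenerate <- sdev == 0
  z <- ifelse(degenerate, 0, (obs - mu) / sdev)
  structure(data.frame(cell_id = cells$cells$cell_id, z = z, observed = obs,
                       degenerate = degenerate, stringsAsFactors = FALSE),
            class = c("EnrichmentScores", "data.frame"),
            B = B, target_size = length(target))
}

#' One-vs-rest cell-type test of enrichment scores with donor random effect
#'
#' Fits `z ~ indicator(cell_type == focal) + (1 | sample_id)` on the cells
#' of the requested stage subset and returns the fixed-effect coefficient
#' with its Wald p value. A singular random-effect fit, or a single
#' donor, falls back to OLS with donor-cluster-robust standard errors
#' (noted in the `method` field).
#'
#' @param scores An `EnrichmentScores` (aligned with `cells`).
#' @param cells The `CellMatrix`.
#' @param focal_type Cell type of interest (must be present in the
#'   subset).
#' @param stage_subset Optional stage-group label(s) to restrict to.
#' @return List: `coef`, `se`, `p`, `method`, `n_cells`, `n_donors`.
#' @export
celltype_mixed_model <- function(scores, cells, focal_type,
                                 stage_subset = NULL) {
  stopifnot(inherits(scores, "EnrichmentScores"), inherits(cells, "CellMatrix"))
  df <- data.frame(z = scores$z,
                   cell_type = cells$cells$cell_type,
                   sample_id = cells$cells$sample_id,
                   stage_group = cells$cells$stage_group,
                   stringsAsFactors = FALSE)
  if (!is.null(stage_subset)) df <- df[df$stage_group %in% stage_subset, ]
  if (!focal_type %in% df$cell_type) {
    stop(sprintf("focal type `%s` absent from the subset", focal_type),
         call. = FALSE)
  }
  df$focal <- as.numeric(df$cell_type == focal_type)
  n_donors <- length(unique(df$sample_id))
  use_fallback <- n_donors < 2L
  fit <- NULL
  if (!use_fallback) {
    fit <- suppressMessages(lme4::lmer(z ~ focal + (1 | sample_id), data = df))
    use_fallback <- lme4::isSingular(fit, tol = 1e-5)
  }
  if (use_fallback) {
    message("random intercept unidentifiable; using cluster-robust OLS")
    ols <- lm(z ~ focal, data = df)
    vc <- if (n_donors >= 2L) {
      sandwich::vcovCL(ols, cluster = df$sample_id)
    } else {
      sandwich::vcovHC(ols)  # one donor: plain heteroskedasticity-robust
    }
    est <- coef(ols)["focal"]
    se <- sqrt(vc["focal", "focal"])
    method <- "ols_cluster_robust"
  } else {
    co <- summary(fit)$coefficients
    est <- co["focal", "Estimate"]
    se <- co["focal", "Std. Error"]
    method <- "lmm"
  }
  list(coef = unname(est), se = unname(se),
       p = unname(2 * pnorm(-abs(est / se))),
       method = method, n_cells = nrow(df), n_donors = n_donors)
}

#' Scan all (cell type, stage group) combinations with BH adjustment
#'
#' Runs [celltype_mixed_model()] for every cell type within every stage
#' group and BH-adjusts the Wald p values across the whole scan.
#'
#' @param scores An `EnrichmentScores`.
#' @param cells The `CellMatrix`.
#' @return Data frame: `cell_type`, `stage_group`, `coef`, `se`, `p`,
#'   `fdr`, `method`.
#' @export
celltype_enrichment_scan <- function(scores, cells) {
  types <- sort(unique(cells$cells$cell_type))
  stages <- sort(unique(cells$cells$stage_group))
  rows <- list()
  for (sg in stages) {
    for (ty in types) {
      r <- celltype_mixed_model(scores, cells, ty, sg)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_type = ty, stage_group = sg, coef = r$coef, se = r$se,
        p = r$p, method = r$method, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$p)
  out
}

#' Paired within-cell contrast of two peak sets' enrichment
#'
#' For the cells of the focal type, compares the per-cell z of set A
#' against set B with a paired t test -- e.g. disease peaks inside the
#' disease TRD vs disease peaks outside any TRD.
#'
#' @param cells A `CellMatrix`.
#' @param set_a,set_b Peak-ID vectors.
#' @param focal_type Cell type whose cells are contrasted.
#' @param B,seed Passed to [cell_set_zscores()].
#' @return List: `mean_difference`, `p`, `n_cells`.
#' @export
enrichment_set_contrast <- function(cells, set_a, set_b, focal_type,
                                    B = 50L, seed = 1L) {
  za <- cell_set_zscores(cells, set_a, B, seed)$z
  zb <- cell_set_zscores(cells, set_b, B, seed + 1L)$z
  keep <- cells$cells$cell_type == focal_type
  tt <- t.test(za[keep], zb[keep], paired = TRUE)
  list(mean_difference = unname(tt$estimate), p = tt$p.value,
       n_cells = sum(keep))
}
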