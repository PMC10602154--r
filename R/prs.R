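#' Restrict a variant weight table to a peak subset's intervals
#'
#' Keeps the variants whose 1-based position falls inside one of the
#' subset peaks. Peaks use the 0-based half-open BED convention, so a
#' variant at position `pos` is inside `[start, end)` iff
#' `start + 1 <= pos <= end`. Overlap is computed with GenomicRanges.
#'
#' @param w Weight table data frame: `variant_id`, `chrom`, `pos`
#'   (1-based), `weight`.
#' @param peaks The full `PeakSet`.
#' @param subset Character vector of peak IDs (must exist in `peaks`).
#' @return The restricted weight table; error when no variant falls in
#'   the intervals.
#' @export
subset_variants_by_intervals <- function(w, peaks, subset) {
  stopifnot(inherits(peaks, "PeakSet"),
            all(c("variant_id", "chrom", "pos", "weight") %in% names(w)))
  unknown <- setdiff(subset, peaks$peak_id)
  if (length(unknown)) stop("subset contains unknown peak IDs", call. = FALSE)
  sub <- peaks[peaks$peak_id %in% subset, , drop = FALSE]
  gr_peaks <- GenomicRanges::GRanges(
    sub$chrom, IRanges::IRanges(start = sub$start + 1L, end = sub$end))
  gr_vars <- GenomicRanges::GRanges(
    w$chrom, IRanges::IRanges(start = w$pos, end = w$pos))
  hits <- GenomicRanges::findOverlaps(gr_vars, gr_peaks)
  keep <- sort(unique(S4Vectors_queryHits(hits)))
  if (!length(keep)) stop("no variants in intervals", call. = FALSE)
  out <- w[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# queryHits without importing S4Vectors wholesale
S4Vectors_queryHits <- function(hits) {
  methods::slot(hits, "from")
}

#' Weighted-dosage polygenic scores
#'
#' `score_s = sum_v dosage_sv * weight_v`. Missing dosages are
#' mean-imputed per variant (count reported via message); variants with
#' more than 20% missingness are dropped with a warning. Scores are
#' invariant to variant order.
#'
#' @param w Weight table (see [subset_variants_by_intervals()]).
#' @param dosages Samples x variants matrix of dosages in `{0, 1, 2}`
#'   (NAs allowed); column names must cover the weight table's variants.
#' @return Named numeric vector of per-sample scores, with attribute
#'   `n_variants`.
#' @export
score_samples <- function(w, dosages) {
  miss <- setdiff(w$variant_id, colnames(dosages))
  if (length(miss)) {
    stop(sprintf("dosage matrix lacks %d weight variant(s)", length(miss)),
         call. = FALSE)
  }
  D <- dosages[, w$variant_id, drop = FALSE]
  na_frac <- colMeans(is.na(D))
  drop <- na_frac > 0.2
  if (any(drop)) {
    warning(sprintf("dropping %d variant(s) with >20%% missing dosages",
                    sum(drop)))
    D <- D[, !drop, drop = FALSE]
    w <- w[!drop, , drop = FALSE]
  }
  n_imputed <- sum(is.na(D))
  if (n_imputed > 0L) {
    message(sprintf("mean-imputing %d missing dosage(s)", n_imputed))
    for (j in which(colSums(is.na(D)) > 0L)) {
      D[is.na(D[, j]), j] <- mean(D[, j], na.rm = TRUE)
    }
  }
  scores <- as.numeric(D %*% w$weight)
  names(scores) <- rownames(dosages)
  attr(scores, "n_variants") <- nrow(w)
  scores
}

#' Case/control association and variance explained of a polygenic score
#'
#' Standardizes the score to unit SD and fits the logistic regression
#' `case ~ score (+ covariates)`, reporting the odds ratio per SD with
#' Wald SE and p, the Nagelkerke pseudo-R-squared as variance explained,
#' and the average variance explained per variant
#' (`r2 / n_variants`). Complete separation triggers a penalized refit by
#' data augmentation (two half-weight pseudo-observations per class),
#' with a notice.
#'
#' @param scores Named per-sample scores from [score_samples()] (or any
#'   numeric vector with an `n_variants` attribute / `n_variants` given).
#' @param meta Sample metadata with `sample_id` and `diagnosis`.
#' @param covariates Optional metadata columns added to the model.
#' @param n_variants Number of variants behind the score; defaults to the
#'   score attribute.
#' @return A `PrsResult` list: `odds_ratio`, `se_log_or`, `p`,
#'   `ci_low`, `ci_high`, `nagelkerke_r2`, `n_variants`,
#'   `variance_per_variant`, `n_samples`, `penalized`.
#' @export
prs_association <- function(scores, meta, covariates = character(0),
                            n_variants = NULL) {
  n_variants <- n_variants %||% attr(scores, "n_variants")
  if (is.null(n_variants) || n_variants < 1L) {
    stop("n_variants must be a positive count", call. = FALSE)
  }
  meta <- meta[match(names(scores), meta$sample_id), , drop = FALSE]
  case <- as.integer(meta$diagnosis == "case")
  if (length(unique(case)) < 2L) stop("both classes required", call. = FALSE)
  s <- if (sd(scores) > 0) as.numeric(scale(scores)) else rep(0, length(scores))
  dat <- data.frame(case = case, score = s)
  for (cv in covariates) dat[[cv]] <- meta[[cv]]
  form <- stats::reformulate(c("score", covariates), response = "case")
  wts <- rep(1, nrow(dat))
  fit <- suppressWarnings(glm(form, family = binomial(), data = dat,
                              weights = wts))
  penalized <- FALSE
  if (!fit$converged || any(fit$fitted.values < 1e-8) ||
      any(fit$fitted.values > 1 - 1e-8)) {
    message("separation detected; refitting with pseudo-observation penalty")
    aug <- dat[c(which(case == 0)[1L], which(case == 1)[1L],
                 which(case == 0)[1L], which(case == 1)[1L]), , drop = FALSE]
    aug$case <- c(1L, 0L, 1L, 0L)
    aug$score <- c(-1, 1, 1, -1) * max(abs(s))
    dat2 <- rbind(dat, aug)
    wts <- c(rep(1, nrow(dat)), rep(0.5, 4L))
    fit <- suppressWarnings(glm(form, family = binomial(), data = dat2,
                                weights = wts))
    penalized <- TRUE
  }
  est <- summary(fit)$coefficients["score", ]
  null_fit <- suppressWarnings(glm(
    stats::reformulate(c("1", covariates), response = "case"),
    family = binomial(), data = if (penalized) dat2 else dat, weights = wts))
  n <- length(case)
  r2 <- (1 - exp((fit$deviance - null_fit$deviance) / n)) /
    (1 - exp(-null_fit$deviance / n))
  structure(list(
    odds_ratio = unname(exp(est["Estimate"])),
    se_log_or = unname(est["Std. Error"]),
    p = unname(est["Pr(>|z|)"]),
    ci_low = unname(exp(est["Estimate"] - 1.96 * est["Std. Error"])),
    ci_high = unname(exp(est["Estimate"] + 1.96 * est["Std. Error"])),
    nagelkerke_r2 = max(0, r2),
    n_variants = as.integer(n_variants),
    variance_per_variant = max(0, r2) / n_variants,
    n_samples = n, penalized = penalized
  ), class = "PrsResult")
}

#' @export
print.PrsResult <- function(x, ...) {
  cat(sprintf(
    "PrsResult: OR/SD = %.3f (p = %.3g), Nagelkerke R2 = %.4f over %d variants\n",
    x$odds_ratio, x$p, x$nagelkerke_r2, x$n_variants))
  cat(sprintf("  variance per variant = %.3g%s\n", x$variance_per_variant,
              if (x$penalized) " [penalized fit]" else ""))
  invisible(x)
}
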