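#' Per-peak case/control differential accessibility
#'
#' Fits, for every peak, the linear model
#' `accessibility ~ group + covariates` and reports the group contrast:
#' log2 fold change (case minus control on the log2 scale), OLS t
#' statistic, two-sided p value and Benjamini-Hochberg FDR across all
#' peaks. The default engine is the ordinary (non-moderated) linear-model
#' t; `moderated = TRUE` routes the same design through limma's
#' empirical-Bayes variance moderation.
#'
#' Constant peaks get `log2fc = 0, p = 1` by convention. Significance
#' downstream means `fdr < 0.05`.
#'
#' @param m An `AccessibilityMatrix`.
#' @param group Metadata column with exactly two levels (>= 3 samples
#'   each); the second factor level (conventionally `"case"`) is the
#'   numerator of the fold change.
#' @param covariates Optional character vector of metadata columns to
#'   adjust for inside the model.
#' @param moderated Use limma empirical-Bayes moderated t instead of OLS.
#' @return A `DifferentialResult` data frame: `peak_id`, `log2fc`,
#'   `t_stat`, `p`, `fdr`, `direction` (`"up"`/`"down"`, NA at log2fc 0).
#' @export
differential_peaks <- function(m, group = "diagnosis", covariates = character(0),
                               moderated = FALSE) {
  stopifnot(inherits(m, "AccessibilityMatrix"))
  g <- m$metadata[[group]]
  if (is.null(g)) stop(sprintf("no metadata column `%s`", group), call. = FALSE)
  g <- droplevels(factor(g))
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels", call. = FALSE)
  if (any(table(g) < 3L)) {
    stop("each group level needs at least 3 samples", call. = FALSE)
  }
  rhs <- c(group, covariates)
  X <- model.matrix(stats::reformulate(rhs), data = transform(m$metadata, .g = g))
  gcol <- 2L  # group indicator sits right after the intercept
  Y <- m$values

  const <- apply(Y, 2L, function(col) max(col) - min(col) == 0)
  if (moderated) {
    if (!requireNamespace("limma", quietly = TRUE)) {
      stop("moderated = TRUE requires the limma package", call. = FALSE)
    }
    fit <- limma::eBayes(limma::lmFit(t(Y), X))
    beta <- fit$coefficients[, gcol]
    tstat <- fit$t[, gcol]
    pval <- fit$p.value[, gcol]
  } else {
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) stop("rank-deficient design", call. = FALSE)
    coefs <- qr.coef(qrX, Y)
    res <- Y - X %*% coefs
    df_res <- nrow(X) - ncol(X)
    sigma2 <- colSums(res^2) / df_res
    XtXinv_gg <- chol2inv(qr.R(qrX))[gcol, gcol]
    beta <- coefs[gcol, ]
    se <- sqrt(sigma2 * XtXinv_gg)
    tstat <- ifelse(se > 0, beta / se, 0)
    pval <- 2 * pt(-abs(tstat), df_res)
  }
  beta[const] <- 0
  tstat[const] <- 0
  pval[const] <- 1
  out <- data.frame(
    peak_id = colnames(Y),
    log2fc = unname(beta),
    t_stat = unname(tstat),
    p = unname(pval),
    fdr = bh_adjust(unname(pval)),
    stringsAsFactors = FALSE
  )
  out$direction <- ifelse(out$log2fc > 0, "up",
                          ifelse(out$log2fc < 0, "down", NA_character_))
  structure(out, class = c("DifferentialResult", "data.frame"),
            group = group, covariates = covariates)
}

#' @export
print.DifferentialResult <- function(x, ...) {
  sig <- x$fdr < 0.05
  cat("DifferentialResult:", nrow(x), "peaks;", sum(sig), "at FDR < 0.05 (",
      sum(sig & x$log2fc > 0), "up /", sum(sig & x$log2fc < 0), "down )\n")
  invisible(x)
}

#' Partition significant peaks by fold-change sign
#'
#' Splits the significant set (`fdr < alpha`) into upregulated
#' (`log2fc > 0`) and downregulated (`log2fc < 0`) peak-ID sets; peaks
#' with log2fc exactly 0 belong to neither.
#'
#' @param d A `DifferentialResult`.
#' @param alpha FDR cutoff defining the significant set (default 0.05).
#' @return List with character vectors `up` and `down`.
#' @export
direction_partition <- function(d, alpha = 0.05) {
  stopifnot(inherits(d, "DifferentialResult"))
  sig <- d[d$fdr < alpha, , drop = FALSE]
  list(up = sig$peak_id[sig$log2fc > 0],
       down = sig$peak_id[sig$log2fc < 0])
}
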