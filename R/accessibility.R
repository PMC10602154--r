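#' Samples-by-peaks accessibility matrix with sample metadata
#'
#' Container for the statistical object of all bulk stages: a numeric
#' samples x peaks matrix of log-scale accessibility plus an aligned
#' per-sample metadata table (diagnosis, age, sex, arbitrary covariates,
#' optional `prs`). Metadata rows align one-to-one with matrix rows by
#' `sample_id`.
#'
#' @param values Numeric matrix (samples x peaks) with row and column
#'   names; no missing values.
#' @param metadata Data frame with a `sample_id` column matching
#'   `rownames(values)`.
#' @return An `AccessibilityMatrix` (list with `values`, `metadata`).
#' @export
accessibility_matrix <- function(values, metadata) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry sample (row) and peak (column) names", call. = FALSE)
  }
  if (anyNA(values)) stop("values contain missing entries", call. = FALSE)
  if (!"sample_id" %in% names(metadata)) {
    stop("metadata must contain a sample_id column", call. = FALSE)
  }
  if (!identical(as.character(metadata$sample_id), rownames(values))) {
    metadata <- metadata[match(rownames(values), metadata$sample_id), ,
                         drop = FALSE]
    if (anyNA(metadata$sample_id)) {
      stop("metadata rows do not align with sample_ids", call. = FALSE)
    }
    rownames(metadata) <- NULL
  }
  structure(list(values = values, metadata = metadata),
            class = "AccessibilityMatrix")
}

#' @export
print.AccessibilityMatrix <- function(x, ...) {
  cat("AccessibilityMatrix:", nrow(x$values), "samples x", ncol(x$values),
      "peaks\n")
  cat("  metadata columns:", paste(setdiff(names(x$metadata), "sample_id"),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Normalize a nonnegative count matrix to log2 counts-per-million
#'
#' Library-size scales each sample to counts-per-million then applies
#' `log2(x + 1)`. Doubling every count of a sample leaves its normalized
#' row unchanged; zero counts map to zero.
#'
#' @param counts Nonnegative samples x peaks matrix with dimnames.
#' @param metadata Per-sample metadata data frame (with `sample_id`).
#' @return An `AccessibilityMatrix` of normalized values.
#' @export
normalize_counts <- function(counts, metadata) {
  stopifnot(is.matrix(counts))
  if (any(counts < 0)) stop("counts must be nonnegative", call. = FALSE)
  depth <- rowSums(counts)
  if (any(depth == 0)) {
    stop(sprintf("all-zero sample: %s",
                 rownames(counts)[which(depth == 0)[1]]), call. = FALSE)
  }
  cpm <- counts / depth * 1e6
  accessibility_matrix(log2(cpm + 1), metadata)
}

#' Residualize accessibility on covariates
#'
#' Replaces each peak column by its least-squares residual on an intercept
#' plus the named metadata covariates. Diagnosis must never be in the
#' covariate list (the disease contrast is estimated downstream, not
#' removed). Residualization is idempotent.
#'
#' @param m An `AccessibilityMatrix`.
#' @param covariates Character vector of metadata column names.
#' @return An `AccessibilityMatrix` of residuals (same dimnames).
#' @export
residualize <- function(m, covariates) {
  stopifnot(inherits(m, "AccessibilityMatrix"))
  missing_cov <- setdiff(covariates, names(m$metadata))
  if (length(missing_cov)) {
    stop(sprintf("unknown covariate(s): %s", paste(missing_cov, collapse = ", ")),
         call. = FALSE)
  }
  if ("diagnosis" %in% covariates) {
    stop("diagnosis must not be residualized out", call. = FALSE)
  }
  X <- model.matrix(stats::reformulate(covariates),
                    data = m$metadata)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("rank-deficient design; collinear column(s): %s",
                 paste(drop, collapse = ", ")), call. = FALSE)
  }
  res <- m$values - X %*% qr.coef(qrX, m$values)
  dimnames(res) <- dimnames(m$values)
  accessibility_matrix(res, m$metadata)
}

#' Map peaks to linked genes via an enhancer-promoter link table
#'
#' @param peaks A `PeakSet`.
#' @param links Data frame with columns `peak_id`, `gene_id` and optional
#'   nonnegative `score`. Rows naming unknown peaks are dropped with a
#'   warning; duplicate (peak, gene) rows collapse.
#' @return Named list mapping every peak ID to a character vector of genes
#'   (empty for unlinked peaks).
#' @export
map_peaks_to_genes <- function(peaks, links) {
  stopifnot(inherits(peaks, "PeakSet"))
  stopifnot(all(c("peak_id", "gene_id") %in% names(links)))
  if (!is.null(links$score) && any(links$score < 0)) {
    stop("link scores must be nonnegative", call. = FALSE)
  }
  unknown <- !(links$peak_id %in% peaks$peak_id)
  if (any(unknown)) {
    warning(sprintf("dropping %d link row(s) with unknown peak_id", sum(unknown)))
    links <- links[!unknown, , drop = FALSE]
  }
  out <- setNames(vector("list", nrow(peaks)), peaks$peak_id)
  out[] <- list(character(0))
  if (nrow(links)) {
    got <- lapply(split(links$gene_id, links$peak_id), function(g) unique(as.character(g)))
    out[names(got)] <- got
  }
  out
}

#' Write / read an accessibility matrix as TSV
#'
#' The matrix is written samples-in-rows with a leading `sample_id`
#' column; metadata goes to a companion table. Round-trips are lossless up
#' to numeric print precision (15 significant digits).
#'
#' @param m An `AccessibilityMatrix`.
#' @param matrix_path,metadata_path Output paths.
#' @return Paths, invisibly.
#' @export
write_accessibility <- function(m, matrix_path, metadata_path) {
  stopifnot(inherits(m, "AccessibilityMatrix"))
  df <- data.frame(sample_id = rownames(m$values),
                   format(m$values, digits = 15, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, matrix_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(m$metadata, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(matrix_path, metadata_path))
}

#' @rdname write_accessibility
#' @export
read_accessibility <- function(matrix_path, metadata_path) {
  df <- read.table(matrix_path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$sample_id
  metadata <- read.table(metadata_path, sep = "\t", header = TRUE,
                         stringsAsFactors = TRUE)
  metadata$sample_id <- as.character(metadata$sample_id)
  if ("diagnosis" %in% names(metadata)) {
    metadata$diagnosis <- factor(metadata$diagnosis,
                                 levels = c("control", "case"))
  }
  accessibility_matrix(values, metadata)
}
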