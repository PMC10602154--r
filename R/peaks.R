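#' Peak universe (`PeakSet`)
#'
#' A `PeakSet` is a validated, sorted data frame of open-chromatin regions
#' with columns `chrom`, `start`, `end` (0-based, half-open, BED
#' convention) and a unique `peak_id`. It is the coordinate backbone of
#' every stage in the package.
#'
#' @param df Data frame with columns `chrom`, `start`, `end` and optionally
#'   `peak_id` (synthesized as `"chrom:start-end"` when absent).
#' @return A `PeakSet` (data frame subclass), sorted by (chrom, start).
#' @export
new_peak_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (is.null(df$peak_id)) {
    df$peak_id <- paste0(df$chrom, ":", df$start, "-", df$end)
  }
  df <- df[, c("chrom", "start", "end", "peak_id")]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  bad <- which(df$start >= df$end)
  if (length(bad)) {
    stop(sprintf("interval with start >= end at row %d", bad[1]), call. = FALSE)
  }
  key <- paste(df$chrom, df$start, df$end)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicated interval: %s", key[duplicated(key)][1]),
         call. = FALSE)
  }
  if (anyDuplicated(df$peak_id)) {
    stop(sprintf("duplicated peak_id: %s", df$peak_id[duplicated(df$peak_id)][1]),
         call. = FALSE)
  }
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("PeakSet", "data.frame"))
}

#' Read peaks from a BED file
#'
#' Accepts 3+ column BED (0-based, half-open). Column 4, when present, is
#' used as the peak ID; otherwise IDs are synthesized as
#' `"chrom:start-end"`. Rows out of genomic order are re-sorted silently;
#' `start >= end` is a parse error reporting the offending line;
#' duplicated intervals are an error.
#'
#' @param path Path to a BED file (comment lines starting `#`, `track` or
#'   `browser` are skipped).
#' @return A `PeakSet`.
#' @export
read_peaks <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno)) {
    return(new_peak_set(data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0))))
  }
  fields <- strsplit(lines[lineno], "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3L)) {
    stop(sprintf("line %d: fewer than 3 BED columns", lineno[which(ncols < 3L)[1]]),
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop(sprintf("line %d: non-numeric coordinate",
                 lineno[which(is.na(start) | is.na(end))[1]]), call. = FALSE)
  }
  bad <- which(start >= end)
  if (length(bad)) {
    stop(sprintf("line %d: start >= end", lineno[bad[1]]), call. = FALSE)
  }
  df <- data.frame(chrom = chrom, start = start, end = end,
                   stringsAsFactors = FALSE)
  if (all(ncols >= 4L)) df$peak_id <- vapply(fields, `[[`, "", 4L)
  new_peak_set(df)
}

#' Write a `PeakSet` (or subset of one) as BED
#'
#' @param peaks A `PeakSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  lines <- sprintf("%s\t%d\t%d\t%s", peaks$chrom, peaks$start, peaks$end,
                   peaks$peak_id)
  writeLines(lines, path)
  invisible(path)
}

#' Export a peak subset as a sorted annotation BED
#'
#' Writes the named subset of the peak universe as a BED file for external
#' heritability-partitioning tools. An empty subset yields a file holding
#' only a header comment.
#'
#' @param peaks The full `PeakSet`.
#' @param subset Character vector of peak IDs (must all exist in `peaks`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_annotation_bed <- function(peaks, subset, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  unknown <- setdiff(subset, peaks$peak_id)
  if (length(unknown)) {
    stop(sprintf("unknown peak IDs in subset: %s",
                 paste(head(unknown, 3), collapse = ", ")), call. = FALSE)
  }
  sub <- peaks[peaks$peak_id %in% subset, , drop = FALSE]
  if (nrow(sub) == 0L) {
    writeLines("# empty annotation", path)
    return(invisible(path))
  }
  sub <- sub[order(sub$chrom, sub$start), , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s", sub$chrom, sub$start, sub$end,
                     sub$peak_id), path)
  invisible(path)
}

#' @export
print.PeakSet <- function(x, ...) {
  cat("PeakSet:", nrow(x), "peaks on", length(unique(x$chrom)),
      "chromosome(s)\n")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

# GRanges view of a PeakSet (1-based closed, the Bioconductor convention).
peaks_to_granges <- function(peaks) {
  stopifnot(inherits(peaks, "PeakSet"))
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    peak_id = peaks$peak_id
  )
}
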