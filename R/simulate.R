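#' Simulation configuration for the synthetic chromatin study
#'
#' Defines the full study design of the synthetic cohort: sample sizes,
#' peak layout along chromosomes, planted cis-regulatory domains (CRDs),
#' their grouping into trans-regulatory domains (TRDs), the case/control
#' disease effect, the coupling between latent disease severity and genetic
#' liability, covariate effects, and the single-cell and genotype layers.
#' All downstream generators ([simulate_bulk()], [simulate_single_cell()],
#' [simulate_genotypes()]) are deterministic functions of this object:
#' identical configurations (including `seed`) give bit-identical output.
#'
#' The defaults describe the reference synthetic cohort used throughout the
#' package tests: 300 samples (120 cases), two chromosomes of 400 peaks
#' each, 20 planted CRDs of 8--25 peaks with within-CRD correlation 0.7,
#' three TRDs with cross-CRD correlation 0.6, a 0.8-SD severity-scaled
#' disease effect on 10% of peaks (concentrated in the disease TRD), and a
#' 0.5 correlation between latent severity and true genetic score.
#'
#' @param n_samples Number of bulk samples.
#' @param n_cases Number of case samples (`< n_samples`). Cases are drawn
#'   with probability increasing in latent severity, so case severity
#'   stochastically dominates control severity.
#' @param n_chromosomes,peaks_per_chromosome Peak-universe layout.
#' @param crd_sizes Integer vector of peaks per planted CRD; CRDs are dealt
#'   round-robin across chromosomes and their per-chromosome totals must
#'   fit within `peaks_per_chromosome`.
#' @param within_crd_correlation Pairwise latent (copula) correlation of
#'   peaks inside a planted CRD, strictly in (0, 1).
#' @param n_trds Number of planted TRDs; CRDs are dealt round-robin, TRD 1
#'   is the disease TRD.
#' @param trd_cross_correlation Target correlation between the mean signals
#'   of two CRDs in the same TRD, strictly in (0, 1).
#' @param disease_effect_size Standardized mean shift per unit severity
#'   applied to affected peaks.
#' @param fraction_affected_peaks Fraction of all peaks carrying the
#'   disease effect; affected peaks fill the disease TRD first, any
#'   remainder is placed on background (outside-CRD) peaks.
#' @param severity_prs_correlation Correlation between latent severity and
#'   the true genetic score, in \[0, 1).
#' @param covariate_effects Named numeric vector of per-covariate
#'   coefficients; supported names are `"sex"`, `"batch"`, `"age"`.
#' @param n_cells,n_cell_types,celltype_signal_fraction Single-cell layer:
#'   number of cells, cell types (at most 26), and the fraction of peaks
#'   with elevated (2x) open probability per cell type.
#' @param n_variants Number of simulated variants for the genotype layer.
#' @param seed Master seed; each simulated object draws from its own
#'   derived RNG stream.
#'
#' @return An object of class `SimConfig` (a validated named list).
#' @seealso [simulate_bulk()], [simulate_single_cell()],
#'   [simulate_genotypes()]
#' @export
sim_config <- function(n_samples = 300L,
                       n_cases = 120L,
                       n_chromosomes = 2L,
                       peaks_per_chromosome = 400L,
                       crd_sizes = rep(c(8L, 10L, 12L, 14L, 16L, 18L, 20L, 22L, 24L, 25L), 2L),
                       within_crd_correlation = 0.7,
                       n_trds = 3L,
                       trd_cross_correlation = 0.6,
                       disease_effect_size = 0.8,
                       fraction_affected_peaks = 0.1,
                       severity_prs_correlation = 0.5,
                       covariate_effects = c(sex = 0.2, batch = 0.3),
                       n_cells = 2000L,
                       n_cell_types = 5L,
                       celltype_signal_fraction = 0.05,
                       n_variants = 1000L,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_cases = as.integer(n_cases),
    n_chromosomes = as.integer(n_chromosomes),
    peaks_per_chromosome = as.integer(peaks_per_chromosome),
    crd_sizes = as.integer(crd_sizes),
    within_crd_correlation = within_crd_correlation,
    n_trds = as.integer(n_trds),
    trd_cross_correlation = trd_cross_correlation,
    disease_effect_size = disease_effect_size,
    fraction_affected_peaks = fraction_affected_peaks,
    severity_prs_correlation = severity_prs_correlation,
    covariate_effects = covariate_effects,
    n_cells = as.integer(n_cells), n_cell_types = as.integer(n_cell_types),
    celltype_signal_fraction = celltype_signal_fraction,
    n_variants = as.integer(n_variants),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "SimConfig")
}

validate_sim_config <- function(cfg) {
  count_fields <- c("n_samples", "n_cases", "n_chromosomes",
                    "peaks_per_chromosome", "n_trds", "n_cells",
                    "n_cell_types", "n_variants")
  for (f in count_fields) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 1L) {
      stop_field(f, "must be a single positive count")
    }
  }
  if (cfg$n_cases >= cfg$n_samples) {
    stop_field("n_cases", "must be smaller than n_samples")
  }
  if (length(cfg$crd_sizes) < 1L || any(cfg$crd_sizes < 2L)) {
    stop_field("crd_sizes", "each planted CRD needs at least 2 peaks")
  }
  chrom_of <- ((seq_along(cfg$crd_sizes) - 1L) %% cfg$n_chromosomes) + 1L
  per_chrom <- tapply(cfg$crd_sizes, chrom_of, sum)
  if (any(per_chrom > cfg$peaks_per_chromosome)) {
    stop_field("crd_sizes",
               "sum of CRD sizes on a chromosome exceeds peaks_per_chromosome")
  }
  for (f in c("within_crd_correlation", "trd_cross_correlation")) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v <= 0 || v >= 1) {
      stop_field(f, "must lie strictly within (0, 1)")
    }
  }
  v <- cfg$severity_prs_correlation
  if (length(v) != 1L || is.na(v) || v < 0 || v >= 1) {
    stop_field("severity_prs_correlation", "must lie in [0, 1)")
  }
  for (f in c("fraction_affected_peaks", "celltype_signal_fraction")) {
    v <- cfg[[f]]
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_field(f, "must lie in [0, 1]")
    }
  }
  if (cfg$n_cell_types > 26L) {
    stop_field("n_cell_types", "exceeds available label space (26 types)")
  }
  if (length(cfg$covariate_effects) &&
      !all(names(cfg$covariate_effects) %in% c("sex", "batch", "age"))) {
    stop_field("covariate_effects",
               "supported covariate names are sex, batch, age")
  }
  invisible(cfg)
}

#' @export
print.SimConfig <- function(x, ...) {
  cat("SimConfig:", x$n_samples, "samples (", x$n_cases, "cases ),",
      x$n_chromosomes, "chromosomes x", x$peaks_per_chromosome, "peaks\n")
  cat("  planted CRDs:", length(x$crd_sizes), "(sizes",
      min(x$crd_sizes), "-", max(x$crd_sizes), "), within-CRD r =",
      x$within_crd_correlation, "\n")
  cat("  TRDs:", x$n_trds, ", cross-CRD r =", x$trd_cross_correlation, "\n")
  cat("  disease effect:", x$disease_effect_size, "on",
      round(100 * x$fraction_affected_peaks, 1), "% of peaks;",
      "severity~PRS r =", x$severity_prs_correlation, "\n")
  cat("  single cell:", x$n_cells, "cells,", x$n_cell_types, "types;",
      "variants:", x$n_variants, "; seed:", x$seed, "\n")
  invisible(x)
}

# ---- internal layout -------------------------------------------------------

# Peak coordinates, planted CRD membership and TRD assignment. All from the
# "peaks" stream so the universe is shared by every generator.
sim_layout <- function(cfg) {
  with_stream(cfg$seed, "peaks", {
    n_chr <- cfg$n_chromosomes
    ppc <- cfg$peaks_per_chromosome
    chrom <- rep(paste0("chr", seq_len(n_chr)), each = ppc)
    width <- round(runif(n_chr * ppc, 200, 1000))
    gap <- round(runif(n_chr * ppc, 500, 5000))
    start <- integer(n_chr * ppc)
    for (c in seq_len(n_chr)) {
      idx <- ((c - 1L) * ppc + 1L):(c * ppc)
      start[idx] <- cumsum(gap[idx]) + c(0L, cumsum(width[idx][-ppc]))
    }
    end <- start + width
    peak_id <- sprintf("p%05d", seq_len(n_chr * ppc))
    peaks <- new_peak_set(data.frame(
      chrom = chrom, start = start, end = end, peak_id = peak_id,
      stringsAsFactors = FALSE
    ))

    n_crd <- length(cfg$crd_sizes)
    crd_chrom <- ((seq_len(n_crd) - 1L) %% n_chr) + 1L
    peak_to_crd <- rep(NA_integer_, n_chr * ppc)
    for (c in seq_len(n_chr)) {
      sizes <- cfg$crd_sizes[crd_chrom == c]
      ids <- which(crd_chrom == c)
      n_bg <- ppc - sum(sizes)
      # spread background peaks evenly around/between planted blocks
      n_gaps <- length(sizes) + 1L
      bg_per_gap <- rep(n_bg %/% n_gaps, n_gaps)
      extra <- n_bg %% n_gaps
      if (extra > 0L) bg_per_gap[seq_len(extra)] <- bg_per_gap[seq_len(extra)] + 1L
      pos <- (c - 1L) * ppc
      for (b in seq_along(sizes)) {
        pos <- pos + bg_per_gap[b]
        peak_to_crd[(pos + 1L):(pos + sizes[b])] <- ids[b]
        pos <- pos + sizes[b]
      }
    }
    names(peak_to_crd) <- peak_id
    crd_to_trd <- ((seq_len(n_crd) - 1L) %% cfg$n_trds) + 1L
    list(peaks = peaks, peak_to_crd = peak_to_crd, crd_to_trd = crd_to_trd)
  })
}

# Affected-peak selection: fill the disease TRD (TRD 1) first, remainder on
# background peaks (flagged). Disease-TRD peaks shift up; background mixed.
sim_affected <- function(cfg, layout) {
  with_stream(cfg$seed, "affected", {
    n_peaks <- length(layout$peak_to_crd)
    n_aff <- round(cfg$fraction_affected_peaks * n_peaks)
    disease_crds <- which(layout$crd_to_trd == 1L)
    pool <- names(layout$peak_to_crd)[layout$peak_to_crd %in% disease_crds]
    bg <- names(layout$peak_to_crd)[is.na(layout$peak_to_crd)]
    take_trd <- min(n_aff, length(pool))
    sel_trd <- if (take_trd > 0L) sample(pool, take_trd) else character(0)
    take_bg <- min(n_aff - take_trd, length(bg))
    sel_bg <- if (take_bg > 0L) sample(bg, take_bg) else character(0)
    data.frame(
      peak_id = c(sel_trd, sel_bg),
      sign = c(rep(1, length(sel_trd)),
               ifelse(runif(length(sel_bg)) < 0.6, 1, -1)),
      background = c(rep(FALSE, length(sel_trd)), rep(TRUE, length(sel_bg))),
      stringsAsFactors = FALSE
    )
  })
}

# Genotype layer shared by simulate_bulk (for the liability score) and
# simulate_genotypes; same stream -> identical draws in both.
sim_genotype_block <- function(cfg, peaks, affected) {
  with_stream(cfg$seed, "genotypes", {
    nv <- cfg$n_variants
    df <- as.data.frame(peaks)
    aff_rows <- which(df$peak_id %in% affected$peak_id)
    other_rows <- setdiff(seq_len(nrow(df)), aff_rows)
    n_aff_v <- if (length(aff_rows)) round(0.15 * nv) else 0L
    n_in_v <- round((if (length(aff_rows)) 0.7 else 0.85) * nv)
    n_out_v <- nv - n_aff_v - n_in_v

    place_in <- function(rows, n) {
      if (n == 0L) return(NULL)
      r <- rows[sample.int(length(rows), n, replace = TRUE)]
      pos <- df$start[r] + 1L + floor(runif(n) * (df$end[r] - df$start[r]))
      data.frame(chrom = df$chrom[r], pos = as.integer(pos), host = r)
    }
    v_aff <- place_in(aff_rows, n_aff_v)
    v_in <- place_in(other_rows, n_in_v)
    # intergenic variants: uniform in the midpoint gaps between peaks
    v_out <- NULL
    if (n_out_v > 0L) {
      gaps <- do.call(rbind, lapply(split(df, df$chrom), function(d) {
        d <- d[order(d$start), ]
        lo <- c(1L, d$end[-nrow(d)] + 50L)
        hi <- d$start - 50L
        ok <- hi > lo
        data.frame(chrom = d$chrom[ok], lo = lo[ok], hi = hi[ok])
      }))
      g <- gaps[sample.int(nrow(gaps), n_out_v, replace = TRUE), ]
      pos <- g$lo + floor(runif(n_out_v) * (g$hi - g$lo))
      v_out <- data.frame(chrom = g$chrom, pos = as.integer(pos), host = NA_integer_)
    }
    vars <- rbind(v_aff, v_in, v_out)
    rownames(vars) <- NULL
    vars$variant_id <- sprintf("v%05d", seq_len(nv))

    maf <- runif(nv, 0.05, 0.5)
    dosages <- matrix(rbinom(cfg$n_samples * nv, 2L, rep(maf, each = cfg$n_samples)),
                      nrow = cfg$n_samples)
    dimnames(dosages) <- list(sprintf("S%04d", seq_len(cfg$n_samples)),
                              vars$variant_id)

    weight <- rnorm(nv, 0, 0.005)
    if (!is.null(v_aff) && nrow(v_aff) > 0L) {
      sgn <- affected$sign[match(df$peak_id[v_aff$host], affected$peak_id)]
      weight[seq_len(nrow(v_aff))] <- sgn * abs(rnorm(nrow(v_aff), 0.08, 0.02))
    }
    g_raw <- as.numeric(dosages %*% weight)
    g <- if (sd(g_raw) > 0) as.numeric(scale(g_raw)) else rep(0, cfg$n_samples)

    list(
      weights = data.frame(variant_id = vars$variant_id, chrom = vars$chrom,
                           pos = vars$pos, weight = weight,
                           stringsAsFactors = FALSE),
      dosages = dosages,
      genetic_score = g
    )
  })
}

# ---- bulk ------------------------------------------------------------------

#' Simulate a bulk samples-by-peaks accessibility matrix with planted truth
#'
#' Draws log-scale accessibility from a Gaussian copula whose correlation
#' matrix is block-diagonal: peaks inside a planted CRD share pairwise
#' correlation `within_crd_correlation`, and CRD factors belonging to the
#' same TRD are coupled so the correlation between CRD mean signals targets
#' `trd_cross_correlation` (TRDs are mutually independent). A latent
#' per-sample severity (correlated `severity_prs_correlation` with the true
#' genetic score from the genotype layer) scales a mean shift
#' `disease_effect_size * severity` on the affected peaks; case labels are
#' drawn with probability increasing in severity so cases sit at the
#' perturbed pole. Covariate effects (sex, batch, age) are added with
#' per-peak loadings. Values are log2-scale; `2^values` is the strictly
#' positive count-scale view of the same matrix.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `BulkSimulation` with elements `peaks` (a
#'   `PeakSet`), `matrix` (an `AccessibilityMatrix` whose metadata carries
#'   diagnosis, age, sex, batch and the observed PRS), and `truth` (a
#'   `GroundTruth` list: `peak_to_crd`, `crd_to_trd`, `affected_peaks`,
#'   `sample_severity`, `sample_prs_true`, `celltype_signal_peaks`,
#'   `variant_weights_true`).
#' @export
simulate_bulk <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  cfg <- config
  layout <- sim_layout(cfg)
  affected <- sim_affected(cfg, layout)
  geno <- sim_genotype_block(cfg, layout$peaks, affected)

  n <- cfg$n_samples
  severity <- with_stream(cfg$seed, "severity", {
    c0 <- cfg$severity_prs_correlation
    eps <- rnorm(n)
    if (c0 > 0 && sd(geno$genetic_score) > 0) {
      c0 * geno$genetic_score + sqrt(1 - c0^2) * eps
    } else eps
  })
  case_idx <- with_stream(cfg$seed, "case", {
    sample.int(n, cfg$n_cases, prob = exp(severity))
  })
  diagnosis <- factor(ifelse(seq_len(n) %in% case_idx, "case", "control"),
                      levels = c("control", "case"))
  covars <- with_stream(cfg$seed, "covariates", {
    data.frame(
      age = runif(n, 25, 90),
      sex = factor(sample(c("M", "F"), n, replace = TRUE)),
      batch = factor(sample(c("b1", "b2"), n, replace = TRUE))
    )
  })

  values <- with_stream(cfg$seed, "bulk", {
    p2c <- layout$peak_to_crd
    n_peaks <- length(p2c)
    rho <- cfg$within_crd_correlation
    tcr <- cfg$trd_cross_correlation
    n_crd <- length(cfg$crd_sizes)
    f <- matrix(rnorm(n * cfg$n_trds), n)          # TRD factors
    h <- matrix(rnorm(n * n_crd), n)               # CRD-private factors
    z <- matrix(rnorm(n * n_peaks), n)             # peak noise / background
    for (c in seq_len(n_crd)) {
      m_c <- cfg$crd_sizes[c]
      var_mean <- rho + (1 - rho) / m_c            # var of the CRD mean signal
      a_c <- min(1, tcr * var_mean / rho)
      g_c <- sqrt(a_c) * f[, layout$crd_to_trd[c]] + sqrt(1 - a_c) * h[, c]
      cols <- which(p2c == c)
      z[, cols] <- sqrt(rho) * g_c + sqrt(1 - rho) * z[, cols]
    }
    if (nrow(affected) > 0L) {
      cols <- match(affected$peak_id, names(p2c))
      z[, cols] <- z[, cols] +
        outer(cfg$disease_effect_size * severity, affected$sign)
    }
    if (length(cfg$covariate_effects)) {
      enc <- list(
        sex = as.numeric(covars$sex == "F"),
        batch = as.numeric(covars$batch == "b2"),
        age = as.numeric(scale(covars$age))
      )
      for (k in names(cfg$covariate_effects)) {
        load_k <- rnorm(n_peaks, 1, 0.3)
        z <- z + outer(cfg$covariate_effects[[k]] * enc[[k]], load_k)
      }
    }
    baseline <- rnorm(n_peaks, 5, 1)
    z <- sweep(z, 2L, baseline, `+`)
    dimnames(z) <- list(rownames(geno$dosages), names(p2c))
    z
  })

  signal_peaks <- with_stream(cfg$seed, "celltypes", {
    ids <- names(layout$peak_to_crd)
    n_sig <- round(cfg$celltype_signal_fraction * length(ids))
    disease_pool <- ids[layout$peak_to_crd %in% which(layout$crd_to_trd == 1L)]
    out <- list()
    for (t in seq_len(cfg$n_cell_types)) {
      if (n_sig == 0L) { out[[t]] <- character(0); next }
      if (t == 1L) {
        take <- min(n_sig, length(disease_pool))
        sel <- sample(disease_pool, take)
        if (take < n_sig) sel <- c(sel, sample(setdiff(ids, sel), n_sig - take))
      } else {
        sel <- sample(ids, n_sig)
      }
      out[[t]] <- sel
    }
    names(out) <- LETTERS[seq_len(cfg$n_cell_types)]
    out
  })

  metadata <- data.frame(
    sample_id = rownames(values), diagnosis = diagnosis,
    age = covars$age, sex = covars$sex, batch = covars$batch,
    prs = geno$genetic_score, stringsAsFactors = FALSE
  )
  truth <- structure(list(
    peak_to_crd = layout$peak_to_crd,
    crd_to_trd = layout$crd_to_trd,
    affected_peaks = affected,
    sample_severity = setNames(severity, rownames(values)),
    sample_prs_true = setNames(geno$genetic_score, rownames(values)),
    celltype_signal_peaks = signal_peaks,
    variant_weights_true = setNames(geno$weights$weight,
                                    geno$weights$variant_id)
  ), class = "GroundTruth")

  structure(list(
    peaks = layout$peaks,
    matrix = accessibility_matrix(values, metadata),
    truth = truth
  ), class = "BulkSimulation")
}

#' @export
print.BulkSimulation <- function(x, ...) {
  cat("BulkSimulation:", nrow(x$matrix$values), "samples x",
      ncol(x$matrix$values), "peaks;",
      sum(!is.na(x$truth$peak_to_crd)), "peaks in",
      length(unique(stats::na.omit(x$truth$peak_to_crd))), "planted CRDs\n")
  invisible(x)
}

# ---- single cell -----------------------------------------------------------

#' Simulate a sparse single-cell ATAC cell-by-peak count matrix
#'
#' Cells carry cell-type, donor (`sample_id`) and developmental stage-group
#' labels. Per-cell depth is log-normal; counts are Poisson around
#' depth-scaled per-peak open probabilities, with a 2x elevated rate for
#' each cell type's planted signal peaks (`truth$celltype_signal_peaks`).
#' Cell type A's signal peaks are drawn from the disease TRD, linking the
#' single-cell enrichment stage to the bulk disease signal. Every cell has
#' positive depth.
#'
#' @param config A [sim_config()] object.
#' @param truth The `GroundTruth` from [simulate_bulk()] under the same
#'   configuration (shared peak universe).
#' @return A list of class `CellMatrix`: `counts` (sparse dgCMatrix, cells
#'   x peaks) and `cells` (per-cell data frame with `cell_id`, `cell_type`,
#'   `sample_id`, `stage_group`, `depth`).
#' @export
simulate_single_cell <- function(config, truth) {
  stopifnot(inherits(config, "SimConfig"), inherits(truth, "GroundTruth"))
  cfg <- config
  peak_ids <- names(truth$peak_to_crd)
  types <- LETTERS[seq_len(cfg$n_cell_types)]
  if (!all(names(truth$celltype_signal_peaks) %in% types) ||
      length(truth$celltype_signal_peaks) < cfg$n_cell_types) {
    stop("n_cell_types exceeds the label space of the supplied ground truth",
         call. = FALSE)
  }
  with_stream(cfg$seed, "cells", {
    n_p <- length(peak_ids)
    donors <- sprintf("SC%02d", 1:8)
    stage_of <- setNames(rep(c("early", "late"), each = 4L), donors)
    cell_type <- sample(types, cfg$n_cells, replace = TRUE)
    donor <- sample(donors, cfg$n_cells, replace = TRUE)
    depth <- pmax(50, round(rlnorm(cfg$n_cells, log(1000), 0.5)))

    base_w <- stats::rgamma(n_p, 1, 1) + 0.1
    # per-donor compositional jitter: a lognormal per-peak factor shared by
    # all of a donor's cells, giving the donor random effect the one-vs-rest
    # mixed model is built to absorb
    donor_w <- sapply(donors, function(d) base_w * exp(rnorm(n_p, 0, 0.2)))
    boost <- lapply(types, function(t) {
      b <- rep(1, n_p)
      b[match(truth$celltype_signal_peaks[[t]], peak_ids)] <- 2
      b
    })
    names(boost) <- types

    counts <- matrix(0L, cfg$n_cells, n_p,
                     dimnames = list(sprintf("c%05d", seq_len(cfg$n_cells)),
                                     peak_ids))
    for (t in types) {
      for (dn in donors) {
        rows <- which(cell_type == t & donor == dn)
        if (!length(rows)) next
        w <- donor_w[, dn] * boost[[t]]
        w <- w / sum(w)
        lam <- outer(depth[rows], w)
        counts[rows, ] <- matrix(rpois(length(lam), lam), nrow = length(rows))
      }
    }
    empty <- which(rowSums(counts) == 0L)
    for (i in empty) counts[i, which.max(base_w)] <- 1L

    structure(list(
      counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
      cells = data.frame(
        cell_id = rownames(counts), cell_type = cell_type,
        sample_id = donor, stage_group = unname(stage_of[donor]),
        depth = as.integer(rowSums(counts)), stringsAsFactors = FALSE
      )
    ), class = "CellMatrix")
  })
}

#' @export
print.CellMatrix <- function(x, ...) {
  cat("CellMatrix:", nrow(x$counts), "cells x", ncol(x$counts), "peaks;",
      length(unique(x$cells$cell_type)), "cell types,",
      length(unique(x$cells$sample_id)), "donors\n")
  invisible(x)
}

# ---- genotypes -------------------------------------------------------------

#' Simulate variant dosages and effect weights tied to the bulk truth
#'
#' Places variants inside affected peaks (which carry most of the nonzero
#' weight, signed like the peak's disease shift), inside other peaks (noise
#' weights), and in intergenic gaps. Dosages are Binomial(2, MAF) with MAF
#' uniform on (0.05, 0.5). The standardized weighted dosage sum is the true
#' genetic score that latent severity was coupled to in [simulate_bulk()];
#' the draws come from the same labelled RNG stream, so the two generators
#' agree exactly regardless of call order.
#'
#' @param config A [sim_config()] object.
#' @param peaks The `PeakSet` from [simulate_bulk()].
#' @param truth The matching `GroundTruth`.
#' @return A list of class `GenotypeSimulation`: `weights` (a `WeightTable`
#'   data frame: variant_id, chrom, pos, weight), `dosages` (samples x
#'   variants integer matrix), `genetic_score` (standardized true score).
#' @export
simulate_genotypes <- function(config, peaks, truth) {
  stopifnot(inherits(config, "SimConfig"), inherits(truth, "GroundTruth"))
  geno <- sim_genotype_block(config, peaks, truth$affected_peaks)
  structure(geno, class = "GenotypeSimulation")
}
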