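#' Run the full regulatory-domain pipeline from one configuration
#'
#' Executes the enabled stages in dependency order -- simulate,
#' differential, crd, trd, stage, scenrich, prs -- writing each stage's
#' outputs in plain-text formats (BED, TSV, MTX, JSON) plus a manifest of
#' parameters and output MD5 hashes. Re-running with the same
#' configuration reproduces identical hashes.
#'
#' @param config Either a named list or a path to a YAML/JSON file.
#'   Recognized entries: `seed` (master seed), `sim` (arguments to
#'   [sim_config()]), `stages` (named logical toggles), and per-stage
#'   parameter lists `differential` (covariates, moderated), `crd`
#'   (r_threshold, min_peaks, alpha), `trd` (k_range, linkage,
#'   up_threshold), `stage` (n_neighbors, d, resolution), `scenrich`
#'   (B), `prs` (covariates).
#' @param output_dir Directory for outputs (created if needed).
#' @return The manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config = list(), output_dir) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("[.]ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("reading YAML configs requires the yaml package", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed %||% 1L
  stages <- utils::modifyList(
    list(simulate = TRUE, differential = TRUE, crd = TRUE, trd = TRUE,
         stage = TRUE, scenrich = TRUE, prs = TRUE),
    as.list(config$stages %||% list()))
  prm <- function(stage, name, default) {
    (config[[stage]] %||% list())[[name]] %||% default
  }
  need <- function(obj, from) {
    if (is.null(obj)) {
      stop(sprintf("missing dependency output: run stage `%s` first", from),
           call. = FALSE)
    }
    obj
  }
  outputs <- character(0)
  emit <- function(path) outputs <<- c(outputs, path)
  tsv <- function(df, name) {
    path <- file.path(output_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(path)
  }

  sim <- diff <- dom <- crd_diff <- trd <- stg <- NULL

  if (stages$simulate) {
    cfg <- do.call(sim_config, c(as.list(config$sim %||% list()),
                                 if (is.null((config$sim %||% list())$seed))
                                   list(seed = seed)))
    sim <- simulate_bulk(cfg)
    write_peaks(sim$peaks, file.path(output_dir, "peaks.bed"))
    emit(file.path(output_dir, "peaks.bed"))
    write_accessibility(sim$matrix, file.path(output_dir, "matrix.tsv"),
                        file.path(output_dir, "metadata.tsv"))
    emit(file.path(output_dir, "matrix.tsv"))
    emit(file.path(output_dir, "metadata.tsv"))
    sc <- simulate_single_cell(cfg, sim$truth)
    write_cell_matrix(sc, output_dir)
    emit(file.path(output_dir, "cells.mtx"))
    emit(file.path(output_dir, "cells_labels.tsv"))
    emit(file.path(output_dir, "cells_peaks.tsv"))
    geno <- simulate_genotypes(cfg, sim$peaks, sim$truth)
    tsv(geno$weights, "weights.tsv")
    tsv(data.frame(variant_id = colnames(geno$dosages),
                   t(geno$dosages), check.names = FALSE), "dosages.tsv")
  }

  if (stages$differential) {
    s <- need(sim, "simulate")
    diff <- differential_peaks(
      s$matrix, group = "diagnosis",
      covariates = prm("differential", "covariates", c("age", "sex", "batch")),
      moderated = prm("differential", "moderated", FALSE))
    tsv(as.data.frame(diff), "differential.tsv")
    part <- direction_partition(diff)
    export_annotation_bed(s$peaks, part$up, file.path(output_dir, "up_peaks.bed"))
    emit(file.path(output_dir, "up_peaks.bed"))
  }

  if (stages$crd) {
    s <- need(sim, "simulate")
    dom <- build_crds(s$matrix, s$peaks,
                      r_threshold = prm("crd", "r_threshold", 0.3),
                      min_peaks = prm("crd", "min_peaks", 3L))
    tsv(dom$domains, "crd_domains.tsv")
    tsv(data.frame(peak_id = names(dom$membership),
                   crd_id = ifelse(is.na(dom$membership), ".", dom$membership)),
        "crd_membership.tsv")
    crd_diff <- two_stage_crd_test(dom, s$matrix,
                                   alpha = prm("crd", "alpha", 0.05))
    tsv(as.data.frame(crd_diff), "crd_differential.tsv")
  }

  if (stages$trd) {
    cd <- need(crd_diff, "crd")
    trd <- tryCatch(
      build_trds(cd, need(dom, "crd"),
                 k_range = prm("trd", "k_range", 2:15),
                 linkage = prm("trd", "linkage", "average")),
      error = function(e) {
        message("trd stage skipped: ", conditionMessage(e))
        NULL
      })
    if (!is.null(trd)) {
      tsv(data.frame(crd_id = names(trd$labels), trd = unname(trd$labels)),
          "trd_labels.tsv")
      tsv(data.frame(k = as.integer(names(trd$gamma_trace)),
                     gamma = unname(trd$gamma_trace)), "gamma_trace.tsv")
      tsv(trd_direction_profile(trd, cd,
                                prm("trd", "up_threshold", 0.75)),
          "trd_directions.tsv")
    }
  }

  if (stages$stage) {
    s <- need(sim, "simulate")
    up <- direction_partition(need(diff, "differential"))$up
    if (length(up) >= 2L) {
      stg <- disease_stage(s$matrix, up,
                           n_neighbors = prm("stage", "n_neighbors", 15L),
                           d = prm("stage", "d", 10L),
                           resolution = prm("stage", "resolution", 1),
                           seed = derive_seed(seed, "stage"))
      tsv(data.frame(sample_id = names(stg$pseudotime),
                     stage = unname(stg$stage),
                     pseudotime = unname(stg$pseudotime),
                     stg$coordinates[, seq_len(min(3L, ncol(stg$coordinates)))]),
          "stages.tsv")
      assoc <- stage_associations(stg, s$matrix$metadata)
      path <- file.path(output_dir, "stage_associations.json")
      jsonlite::write_json(assoc[!vapply(assoc, is.null, TRUE)], path,
                           auto_unbox = TRUE, digits = 10)
      emit(path)
    } else {
      message("stage skipped: fewer than 2 upregulated peaks")
    }
  }

  if (stages$scenrich) {
    s <- need(sim, "simulate")
    sc <- simulate_single_cell(
      do.call(sim_config, c(as.list(config$sim %||% list()),
                            if (is.null((config$sim %||% list())$seed))
                              list(seed = seed))), s$truth)
    target <- s$truth$celltype_signal_peaks[["A"]]
    if (length(target) >= 10L) {
      z <- cell_set_zscores(sc, target, B = prm("scenrich", "B", 50L),
                            seed = derive_seed(seed, "scenrich"))
      tsv(as.data.frame(z), "scenrich_z.tsv")
      tsv(celltype_enrichment_scan(z, sc), "scenrich_stats.tsv")
    } else {
      message("scenrich skipped: target set below 10 peaks")
    }
  }

  if (stages$prs) {
    s <- need(sim, "simulate")
    cfg <- do.call(sim_config, c(as.list(config$sim %||% list()),
                                 if (is.null((config$sim %||% list())$seed))
                                   list(seed = seed)))
    geno <- simulate_genotypes(cfg, s$peaks, s$truth)
    res <- list(genome_wide = prs_association(
      score_samples(geno$weights, geno$dosages), s$matrix$metadata,
      covariates = prm("prs", "covariates", character(0))))
    path <- file.path(output_dir, "prs_results.json")
    jsonlite::write_json(lapply(res, unclass), path, auto_unbox = TRUE,
                         digits = 10)
    emit(path)
  }

  manifest <- list(
    seed = seed,
    stages = stages,
    parameters = config[setdiff(names(config), c("seed", "stages"))],
    outputs = lapply(setNames(nm = basename(outputs)), function(b) {
      unname(tools::md5sum(file.path(output_dir, b)))
    })
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write a `CellMatrix` as MTX plus label tables
#'
#' @param sc A `CellMatrix`.
#' @param dir Output directory.
#' @return Paths, invisibly.
#' @export
write_cell_matrix <- function(sc, dir) {
  stopifnot(inherits(sc, "CellMatrix"))
  mtx <- file.path(dir, "cells.mtx")
  Matrix::writeMM(sc$counts, mtx)
  write.table(sc$cells, file.path(dir, "cells_labels.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(peak_id = colnames(sc$counts)),
              file.path(dir, "cells_peaks.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(mtx, file.path(dir, c("cells_labels.tsv", "cells_peaks.tsv"))))
}

#' Read a `CellMatrix` written by [write_cell_matrix()]
#'
#' @param dir Directory holding `cells.mtx`, `cells_labels.tsv`,
#'   `cells_peaks.tsv`.
#' @return A `CellMatrix`.
#' @export
read_cell_matrix <- function(dir) {
  counts <- methods::as(Matrix::readMM(file.path(dir, "cells.mtx")),
                        "CsparseMatrix")
  cells <- read.table(file.path(dir, "cells_labels.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  peaks <- read.table(file.path(dir, "cells_peaks.tsv"), sep = "\t",
                      header = TRUE, stringsAsFactors = FALSE)
  dimnames(counts) <- list(cells$cell_id, peaks$peak_id)
  structure(list(counts = counts, cells = cells), class = "CellMatrix")
}
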