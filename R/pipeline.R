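# End-to-end reproducible runs: a validated run configuration, stage
# orchestration (simulate -> quantify -> metrics -> mif -> mafdyn ->
# stability) with a checksummed manifest, and a bundled fixture
# generator exercising every stage.

#' Build a run configuration
#'
#' All stage parameters live in named blocks mirroring the stage
#' functions; unknown keys are rejected so typos cannot silently fall
#' back to defaults. The thresholds of the published pipeline (0.95
#' dominance, |delta MAF| 0.15 at p 0.05, FDR 0.05, 1% co-occurrence,
#' 3/7/30/100-read cutoffs, burn-in 2500) are the defaults. The
#' configuration round-trips through YAML unchanged.
#'
#' @param seed Global seed; each stage derives its own child seed.
#' @param library List: `n`, `length`, `min_dist`.
#' @param simulate Overrides for [sim_params()].
#' @param quantify List: `spacer_mismatch`, `mismatch_anywhere`.
#' @param metrics List: `threshold`, `min_count`.
#' @param mif List: `ci` (interval type).
#' @param mafdyn List: `delta_cut`, `p_cut`, `fdr`, `frac_cut`.
#' @param stability List: `burn_in`, `alpha`, `baseline`.
#' @return Named list of class `RunConfig`.
#' @export
run_config <- function(seed = 1L, library = list(), simulate = list(),
                       quantify = list(), metrics = list(), mif = list(),
                       mafdyn = list(), stability = list()) {
  defaults <- list(
    seed = 1L,
    library = list(n = 100L, length = 18L, min_dist = 3L),
    simulate = unclass(sim_params()),
    quantify = list(spacer_mismatch = 1L, mismatch_anywhere = FALSE),
    metrics = list(threshold = 0.95, min_count = 1L),
    mif = list(ci = "wald"),
    mafdyn = list(delta_cut = 0.15, p_cut = 0.05, fdr = 0.05,
                  frac_cut = 0.01),
    stability = list(burn_in = 250L, alpha = 0.05, baseline = "global"))
  supplied <- list(seed = seed, library = library, simulate = simulate,
                   quantify = quantify, metrics = metrics, mif = mif,
                   mafdyn = mafdyn, stability = stability)
  cfg <- defaults
  cfg$seed <- as.integer(seed)
  for (block in setdiff(names(defaults), "seed")) {
    extra <- setdiff(names(supplied[[block]]), names(defaults[[block]]))
    if (length(extra)) {
      stop(sprintf("unknown key(s) in config block '%s': %s", block,
                   paste(extra, collapse = ", ")))
    }
    cfg[[block]][names(supplied[[block]])] <- supplied[[block]]
  }
  class(cfg) <- c("RunConfig", "list")
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param config A `RunConfig`.
#' @param path YAML path.
#' @return `read_run_config` returns a validated `RunConfig`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  extra <- setdiff(names(raw),
                   c("seed", "library", "simulate", "quantify", "metrics",
                     "mif", "mafdyn", "stability"))
  if (length(extra)) {
    stop("unknown top-level config key(s): ", paste(extra, collapse = ", "))
  }
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Simulates a barcoded experiment, quantifies it, computes the clonal
#' report, fits the bundled limiting-dilution assays, runs the delta-MAF
#' stage on a simulated subclone phantom, and tests cluster stability on
#' a simulated trace. All outputs are written under `out_dir` and listed
#' in a manifest with content checksums; rerunning with the same config
#' and seed reproduces identical checksums.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created; existing files overwritten).
#' @return The manifest (list), invisibly written as `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "RunConfig"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage_log <- list()
  t0 <- proc.time()[["elapsed"]]

  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      writeLines("incomplete", file.path(out_dir, "INCOMPLETE"))
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
    stage_log[[name]] <<- sprintf("ok (%.1fs)",
                                  proc.time()[["elapsed"]] - t0)
    res
  }

  # -- simulate ------------------------------------------------------
  sim <- run_stage("simulate", {
    lib <- make_half_library(config$library$n, config$library$length,
                             config$library$min_dist,
                             seed = derive_seed(config$seed, "library"))
    sp <- do.call(sim_params, config$simulate)
    sim <- simulate_experiment(sp, lib,
                               seed = derive_seed(config$seed, "simulate"))
    write_half_library(lib, file.path(out_dir, "half_library.fasta"))
    write_sample_fastq(sim, file.path(out_dir, "fastq"))
    utils::write.csv(sim$samples, file.path(out_dir, "samples.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = config$seed, params = config$simulate),
      file.path(out_dir, "sim_params.json"), auto_unbox = TRUE)
    list(sim = sim, lib = lib)
  })

  # -- quantify ------------------------------------------------------
  cm <- run_stage("quantify", {
    cm <- count_pairs(sim$sim$reads, sim$lib,
                      spacer_mismatch = config$quantify$spacer_mismatch,
                      mismatch_anywhere = config$quantify$mismatch_anywhere)
    write_count_matrix(cm, out_dir)
    cm
  })

  # -- metrics -------------------------------------------------------
  run_stage("metrics", {
    rep <- clonal_report(cm, sim$sim$samples,
                         threshold = config$metrics$threshold,
                         min_count = config$metrics$min_count)
    utils::write.table(rep$per_sample,
                       file.path(out_dir, "per_sample_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(rep$per_metastasis,
                       file.path(out_dir, "per_metastasis_metrics.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    rep
  })

  # -- mif -----------------------------------------------------------
  run_stage("mif", {
    fits <- lapply(example_dilution_assays(), fit_single_hit,
                   ci = config$mif$ci)
    jsonlite::write_json(
      lapply(fits, function(f) {
        list(percent = round(f$percent, 1),
             ci_low_percent = round(f$percent_low, 1),
             ci_high_percent = round(f$percent_high, 1), flag = f$flag)
      }),
      file.path(out_dir, "mif.json"), auto_unbox = TRUE, digits = NA)
    fits
  })

  # -- mafdyn --------------------------------------------------------
  run_stage("mafdyn", {
    ph <- subclone_phantom(
      genotype = rbind(clonal = c(1, 1), private = c(0, 1)),
      mixing = cbind(P1 = c(0.9, 0.1), P2 = c(0.9, 0.1),
                     P3 = c(0.9, 0.1), M1 = c(0.3, 0.7),
                     M2 = c(0.3, 0.7), M3 = c(0.3, 0.7)),
      depth = 1500)
    vt <- simulate_maf_table(ph, seed = derive_seed(config$seed, "maf"))
    dm <- delta_maf(vt, group_met = c("M1", "M2", "M3"),
                    group_primary = c("P1", "P2", "P3"),
                    delta_cut = config$mafdyn$delta_cut,
                    p_cut = config$mafdyn$p_cut)
    utils::write.table(dm, file.path(out_dir, "delta_maf.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    dm
  })

  # -- stability -----------------------------------------------------
  run_stage("stability", {
    truth <- stats::setNames(rep(c("c1", "c2", "c3"), each = 6),
                             sprintf("var%03d", 1:18))
    tr <- simulate_assignment_trace(
      truth, n_iters = 1000,
      flip_rate = c(c1 = 0.05, c2 = 0.05, c3 = 0.45),
      seed = derive_seed(config$seed, "trace"))
    write_trace_tsv(tr, file.path(out_dir, "trace.tsv"))
    rep <- test_cluster_robustness(tr, burn_in = config$stability$burn_in,
                                   alpha = config$stability$alpha,
                                   baseline = config$stability$baseline)
    utils::write.table(rep$clusters,
                       file.path(out_dir, "stability.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    rep
  })

  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.json"))
  manifest <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(
      write_run_config(config, file.path(out_dir, "config.yaml")))),
    stages = stage_log,
    files = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out_dir, files))), files)))
  manifest$files[["config.yaml"]] <- unname(
    tools::md5sum(file.path(out_dir, "config.yaml")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

#' Demo configuration for a quick end-to-end run
#'
#' A scaled-down [run_config()] (20,000 cells per mouse, 50,000 reads
#' per sample, 100-sequence half-library) that exercises every stage in
#' well under five minutes on one CPU.
#'
#' @param seed Global seed.
#' @return A `RunConfig`.
#' @export
demo_config <- function(seed = 1L) {
  run_config(
    seed = seed,
    library = list(n = 100L),
    simulate = list(n_cells = 2e4,
                    mice = list(A = c("lung", "lung", "liver"),
                                B = c("lung", "liver")),
                    seeders_per_lesion = 50,
                    reads_per_sample = 5e4))
}

#' Write / read a CountMatrix as TSV
#'
#' `counts.tsv` and `cpm.tsv` (rows keyed `half1:half2`, one column per
#' sample) plus `quantify_log.json`.
#'
#' @param cm A `CountMatrix`.
#' @param dir Output directory.
#' @return `read_count_matrix` rebuilds a `CountMatrix` (log restored
#'   from JSON).
#' @export
write_count_matrix <- function(cm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cdf <- data.frame(barcode = rownames(cm$counts), cm$counts,
                    check.names = FALSE)
  utils::write.table(cdf, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pdf <- data.frame(barcode = rownames(cm$cpm), cm$cpm,
                    check.names = FALSE)
  utils::write.table(pdf, file.path(dir, "cpm.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(cm$log, file.path(dir, "quantify_log.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(dir) {
  cdf <- utils::read.delim(file.path(dir, "counts.tsv"),
                           check.names = FALSE)
  pdf <- utils::read.delim(file.path(dir, "cpm.tsv"),
                           check.names = FALSE)
  counts <- as.matrix(cdf[, -1, drop = FALSE])
  rownames(counts) <- cdf$barcode
  storage.mode(counts) <- "integer"
  cpm <- as.matrix(pdf[, -1, drop = FALSE])
  rownames(cpm) <- pdf$barcode
  halves <- do.call(rbind, strsplit(cdf$barcode, ":", fixed = TRUE))
  log <- jsonlite::read_json(file.path(dir, "quantify_log.json"),
                             simplifyVector = TRUE)
  structure(list(
    barcodes = data.frame(half1 = halves[, 1], half2 = halves[, 2],
                          key = cdf$barcode, stringsAsFactors = FALSE),
    samples = colnames(counts), counts = counts, cpm = cpm, log = log),
    class = "CountMatrix")
}

#' Generate a small bundled fixture set
#'
#' Writes, under `dir`: a 100-sequence half-library FASTA; per-sample
#' FASTQs for 2 mice x (1 MFP + 2 lung + 1 liver) at `reads_per_sample`
#' reads each plus the sample sheet; the bundled limiting-dilution CSVs;
#' a subclone-phantom variant table TSV; and a 500-iteration assignment
#' trace TSV. Everything is generated from `seed`.
#'
#' @param seed Integer seed.
#' @param dir Output directory.
#' @param reads_per_sample Reads per FASTQ (default 50,000).
#' @return Named list of paths (and the ground-truth `sim` object).
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("fixtures"),
                          reads_per_sample = 5e4) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  lib <- make_half_library(100L, 18L, 3L,
                           seed = derive_seed(seed, "library"))
  write_half_library(lib, file.path(dir, "half_library.fasta"))
  sp <- sim_params(
    n_cells = 2e4, mice = list(m1 = c("lung", "lung", "liver"),
                               m2 = c("lung", "lung", "liver")),
    seeders_per_lesion = 50, reads_per_sample = reads_per_sample,
    error_rate = 0, junk_fraction = 0)
  sim <- simulate_experiment(sp, lib, seed = derive_seed(seed, "sim"))
  fq <- write_sample_fastq(sim, file.path(dir, "fastq"))
  utils::write.csv(sim$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE)
  for (nm in names(example_dilution_assays())) {
    utils::write.csv(example_dilution_assays()[[nm]],
                     file.path(dir, paste0("dilution_", nm, ".csv")),
                     row.names = FALSE)
  }
  ph <- subclone_phantom(
    genotype = rbind(clonal = c(1, 1), private = c(0, 1)),
    mixing = cbind(P1 = c(0.9, 0.1), P2 = c(0.9, 0.1), P3 = c(0.9, 0.1),
                   M1 = c(0.3, 0.7), M2 = c(0.3, 0.7), M3 = c(0.3, 0.7)),
    depth = 1500)
  vt <- simulate_maf_table(ph, seed = derive_seed(seed, "maf"))
  utils::write.table(vt, file.path(dir, "variant_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth <- stats::setNames(rep(c("c1", "c2", "c3"), each = 6),
                           sprintf("var%03d", 1:18))
  tr <- simulate_assignment_trace(
    truth, n_iters = 500,
    flip_rate = c(c1 = 0.05, c2 = 0.05, c3 = 0.45),
    seed = derive_seed(seed, "trace"))
  write_trace_tsv(tr, file.path(dir, "trace.tsv"))
  list(dir = dir, library = file.path(dir, "half_library.fasta"),
       fastq = fq, samples = file.path(dir, "samples.csv"),
       variant_table = file.path(dir, "variant_table.tsv"),
       trace = file.path(dir, "trace.tsv"), sim = sim,
       trace_truth = truth)
}
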