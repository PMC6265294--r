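# Variant-level computations: mutant allele frequencies and consensus
# filters, delta-MAF enrichment between metastases and primary tumors,
# de novo mutation criteria, the read co-occurrence repeat-artifact
# filter, sample-similarity summaries, and the qPCR human-fraction
# formula.
#
# The long-format variant table carries one row per (variant, sample):
# variant_id, sample_id, ref_reads, alt_reads, and per-variant metadata
# (n_callers, germline_vaf, in_population_db, is_silent, region_class)
# plus per-sample platform ("WES" or "targeted"). MAF = alt / (ref + alt)
# where coverage is positive; zero-coverage MAFs are undefined (NA),
# never imputed as 0.

#' Compute MAF on a variant table
#'
#' Adds/overwrites the `maf` column; rows with zero coverage get `NA`.
#'
#' @param table Variant data.frame with `ref_reads` and `alt_reads`.
#' @return The table with a `maf` column.
#' @export
add_maf <- function(table) {
  cov <- table$ref_reads + table$alt_reads
  table$maf <- ifelse(cov > 0, table$alt_reads / cov, NA_real_)
  table
}

#' Consensus variant filters
#'
#' Applies the platform-specific elimination rules. In `"WES"` mode a
#' variant is removed when any of these hold: silent or
#' intergenic/intronic; called by only one variant caller; total coverage
#' (ref + alt) below 30 in all samples; alternate coverage below 5 in all
#' samples; germline VAF at or above 1%; present in the population
#' database. In `"targeted"` mode a variant is kept only if called by at
#' least 2 callers in at least one sample, and its per-sample `detected`
#' status requires at least 3 mutant reads; `"targeted_barcoded"`
#' additionally requires per-sample total coverage of at least 100 reads
#' for detection.
#'
#' @param table Long-format variant data.frame (see module header).
#' @param mode One of `"WES"`, `"targeted"`, `"targeted_barcoded"`.
#' @param min_coverage,min_alt,germline_max,min_mutant_reads,
#'   min_targeted_coverage Rule thresholds, defaulting to the pipeline's
#'   published cutoffs (30 / 5 / 1% / 3 / 100).
#' @return List with `table` (retained rows, `maf` recomputed, plus a
#'   logical `detected` column in targeted modes) and `log` (per-rule
#'   variant drop counts).
#' @export
consensus_filter <- function(table, mode = c("WES", "targeted",
                                             "targeted_barcoded"),
                             min_coverage = 30, min_alt = 5,
                             germline_max = 0.01, min_mutant_reads = 3,
                             min_targeted_coverage = 100) {
  mode <- match.arg(mode)
  need <- c("variant_id", "sample_id", "ref_reads", "alt_reads",
            "n_callers")
  if (mode == "WES") {
    need <- c(need, "germline_vaf", "in_population_db", "is_silent",
              "region_class")
  }
  missing_cols <- setdiff(need, names(table))
  if (length(missing_cols)) {
    stop("variant table is missing column(s) required for mode ", mode,
         ": ", paste(missing_cols, collapse = ", "))
  }
  table <- add_maf(table)
  drop_log <- list()
  variants <- unique(table$variant_id)

  if (mode == "WES") {
    meta <- table[!duplicated(table$variant_id), ]
    cov <- table$ref_reads + table$alt_reads
    max_cov <- tapply(cov, table$variant_id, max)
    max_alt <- tapply(table$alt_reads, table$variant_id, max)
    bad_region <- meta$variant_id[
      meta$is_silent | meta$region_class %in% c("intergenic", "intronic")]
    one_caller <- meta$variant_id[meta$n_callers < 2]
    low_cov <- names(max_cov)[max_cov < min_coverage]
    low_alt <- names(max_alt)[max_alt < min_alt]
    germline <- meta$variant_id[meta$germline_vaf >= germline_max]
    popdb <- meta$variant_id[meta$in_population_db]
    drop_log <- list(silent_or_noncoding = length(bad_region),
                     single_caller = length(one_caller),
                     low_total_coverage = length(low_cov),
                     low_alt_coverage = length(low_alt),
                     germline = length(germline),
                     population_db = length(popdb))
    dropped <- unique(c(bad_region, one_caller, low_cov, low_alt,
                        germline, popdb))
    kept <- table[!table$variant_id %in% dropped, , drop = FALSE]
  } else {
    one_caller <- variants[
      tapply(table$n_callers, table$variant_id, max)[variants] < 2]
    drop_log <- list(single_caller = length(one_caller))
    kept <- table[!table$variant_id %in% one_caller, , drop = FALSE]
    detected <- kept$alt_reads >= min_mutant_reads
    if (mode == "targeted_barcoded") {
      detected <- detected &
        (kept$ref_reads + kept$alt_reads) >= min_targeted_coverage
    }
    kept$detected <- detected
  }
  drop_log$n_input_variants <- length(variants)
  drop_log$n_retained_variants <- length(unique(kept$variant_id))
  drop_log$n_dropped_variants <-
    drop_log$n_input_variants - drop_log$n_retained_variants
  list(table = kept, log = drop_log)
}

#' Delta-MAF enrichment between metastases and primary tumors
#'
#' For each variant, `delta_maf` is the mean MAF across the metastasis
#' samples minus the mean MAF across the primary (MFP) samples; the
#' p-value is a two-sample two-tailed t-test (Welch by default). A
#' variant is classified `enriched` when `delta_maf >= delta_cut` and
#' `p <= p_cut`, `depleted` when `delta_maf <= -delta_cut` and
#' `p <= p_cut`, else `neutral`. Variants with fewer than 2 defined MAFs
#' in either group are flagged `untestable`.
#'
#' @param table Variant data.frame (long format, `maf` computed if
#'   absent).
#' @param group_met,group_primary Character vectors of sample ids.
#' @param delta_cut Minimum absolute MAF change (default 0.15).
#' @param p_cut Significance threshold (default 0.05, unadjusted).
#' @param var_equal Pooled-variance Student test instead of Welch.
#' @return Data.frame with one row per variant: `variant_id`,
#'   `mean_met`, `mean_primary`, `delta_maf`, `t`, `p`, `class`.
#' @export
delta_maf <- function(table, group_met, group_primary, delta_cut = 0.15,
                      p_cut = 0.05, var_equal = FALSE) {
  if (!"maf" %in% names(table)) table <- add_maf(table)
  variants <- unique(table$variant_id)
  out <- data.frame(variant_id = variants, mean_met = NA_real_,
                    mean_primary = NA_real_, delta_maf = NA_real_,
                    t = NA_real_, p = NA_real_, class = "untestable",
                    stringsAsFactors = FALSE)
  for (i in seq_along(variants)) {
    rows <- table[table$variant_id == variants[i], ]
    met <- rows$maf[rows$sample_id %in% group_met]
    pri <- rows$maf[rows$sample_id %in% group_primary]
    met <- met[!is.na(met)]
    pri <- pri[!is.na(pri)]
    if (length(met) < 2L || length(pri) < 2L) next
    dm <- mean(met) - mean(pri)
    if (stats::sd(met) == 0 && stats::sd(pri) == 0) {
      tt <- if (mean(met) == mean(pri)) {
        list(statistic = 0, p.value = 1)
      } else {
        list(statistic = Inf, p.value = 0)
      }
    } else {
      ht <- stats::t.test(met, pri, var.equal = var_equal)
      tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    }
    cls <- "neutral"
    if (dm >= delta_cut && tt$p.value <= p_cut) cls <- "enriched"
    if (dm <= -delta_cut && tt$p.value <= p_cut) cls <- "depleted"
    out$mean_met[i] <- mean(met)
    out$mean_primary[i] <- mean(pri)
    out$delta_maf[i] <- dm
    out$t[i] <- tt$statistic
    out$p[i] <- tt$p.value
    out$class[i] <- cls
  }
  out
}

#' De novo metastasis mutation candidates
#'
#' A candidate de novo mutation must look non-mutant in every MFP tumor
#' on both platforms — zero alternate reads by WES and fewer than
#' `targeted_nonmutant_max` (default 7) mutant reads by targeted deep
#' sequencing — and be detected (at least `min_mutant_reads` mutant
#' reads, default 3) in at least one metastasis of exactly one mouse;
#' the same mutation arising independently in several mice is treated as
#' implausible and excluded.
#'
#' @param table Variant data.frame with a `platform` column
#'   (`"WES"`/`"targeted"`).
#' @param sample_meta Sample sheet (`sample_id`, `mouse`, `site`).
#' @param targeted_nonmutant_max Mutant-read count below which a targeted
#'   MFP measurement counts as non-mutant (default 7).
#' @param min_mutant_reads Detection threshold in metastases (default 3).
#' @return Character vector of candidate variant ids.
#' @export
de_novo_candidates <- function(table, sample_meta,
                               targeted_nonmutant_max = 7,
                               min_mutant_reads = 3) {
  if (!"platform" %in% names(table)) {
    stop("variant table needs a 'platform' column")
  }
  tab <- merge(table, sample_meta[, c("sample_id", "mouse", "site")],
               by = "sample_id")
  mfp <- tab[tab$site == "MFP", ]
  met <- tab[tab$site %in% c("lung", "liver", "brain"), ]
  if (!all(c("WES", "targeted") %in% mfp$platform)) {
    stop("MFP samples must be present on both WES and targeted platforms")
  }
  candidates <- character(0)
  for (v in unique(tab$variant_id)) {
    m <- mfp[mfp$variant_id == v, ]
    if (nrow(m) == 0L) next
    wes_clean <- all(m$alt_reads[m$platform == "WES"] == 0)
    tgt_clean <- all(m$alt_reads[m$platform == "targeted"] <
                       targeted_nonmutant_max)
    if (!(wes_clean && tgt_clean)) next
    mm <- met[met$variant_id == v &
                met$alt_reads >= min_mutant_reads, ]
    if (nrow(mm) > 0L && length(unique(mm$mouse)) == 1L) {
      candidates <- c(candidates, v)
    }
  }
  candidates
}

#' Read co-occurrence repeat-artifact filter
#'
#' Alignment artifacts from repeat regions show up as pairs of mutations
#' that co-occur on the same reads far more often than independence
#' predicts. Each tested pair's 2x2 read table (`n_both`, `n_only_a`,
#' `n_only_b`, `n_neither`) gets a chi-square test of independence
#' (Pearson, no continuity correction; Fisher's exact test when any
#' expected cell is below 5); p-values are Benjamini-Hochberg adjusted
#' across all tested pairs. A pair is flagged when its adjusted p is
#' below `fdr`, and discarded — both member mutations removed — when it
#' is flagged and co-occurs in more than `frac_cut` of the spanning
#' reads.
#'
#' @param cooc Data.frame with columns `mut_a`, `mut_b`, `n_both`,
#'   `n_only_a`, `n_only_b`, `n_neither`.
#' @param fdr False-discovery-rate threshold (default 0.05).
#' @param frac_cut Co-occurrence read-fraction cutoff (default 0.01).
#' @param fisher_fallback Use Fisher's exact test for small expected
#'   counts (default TRUE).
#' @return List with `pairs` (input plus `p`, `q`, `flagged`,
#'   `discarded`, `cooc_fraction`, `untestable`) and
#'   `discarded_mutations` (character vector).
#' @export
repeat_artifact_filter <- function(cooc, fdr = 0.05, frac_cut = 0.01,
                                   fisher_fallback = TRUE) {
  need <- c("mut_a", "mut_b", "n_both", "n_only_a", "n_only_b",
            "n_neither")
  if (!all(need %in% names(cooc))) {
    stop("co-occurrence table must have columns: ",
         paste(need, collapse = ", "))
  }
  n <- nrow(cooc)
  p <- rep(NA_real_, n)
  untestable <- rep(FALSE, n)
  total <- cooc$n_both + cooc$n_only_a + cooc$n_only_b + cooc$n_neither
  for (i in seq_len(n)) {
    m <- matrix(c(cooc$n_both[i], cooc$n_only_a[i],
                  cooc$n_only_b[i], cooc$n_neither[i]), 2L, 2L)
    if (total[i] == 0L || any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      untestable[i] <- TRUE
      next
    }
    expected <- outer(rowSums(m), colSums(m)) / total[i]
    p[i] <- if (fisher_fallback && any(expected < 5)) {
      stats::fisher.test(m)$p.value
    } else {
      suppressWarnings(stats::chisq.test(m, correct = FALSE)$p.value)
    }
  }
  q <- rep(NA_real_, n)
  q[!untestable] <- stats::p.adjust(p[!untestable], method = "BH")
  frac <- ifelse(total > 0, cooc$n_both / total, NA_real_)
  flagged <- !untestable & q < fdr
  discarded <- flagged & frac > frac_cut
  cooc$p <- p
  cooc$q <- q
  cooc$cooc_fraction <- frac
  cooc$flagged <- flagged
  cooc$discarded <- discarded
  cooc$untestable <- untestable
  list(pairs = cooc,
       discarded_mutations =
         sort(unique(c(cooc$mut_a[discarded], cooc$mut_b[discarded]))))
}

#' Percent human genomic DNA from qPCR
#'
#' `100 * 2^(-dct_human) / (2^(-dct_human) + 2^(-dct_mouse))`, the
#' delta-Ct partition of a xenograft sample's DNA between the human and
#' mouse species-specific assays.
#'
#' @param dct_human,dct_mouse Delta-Ct values (cycles) for the human and
#'   mouse assays; vectorized.
#' @return Percent human gDNA.
#' @export
human_fraction <- function(dct_human, dct_mouse) {
  h <- 2^(-dct_human)
  m <- 2^(-dct_mouse)
  100 * h / (h + m)
}

#' Sample similarity from MAF profiles
#'
#' Pairwise Pearson correlation over the MAFs defined in both samples of
#' each pair, and complete-linkage hierarchical clustering on Euclidean
#' distances between MAF vectors (variants with a defined MAF in every
#' sample). Leaf order is made deterministic by seeding the clustering
#' input in sample-id order.
#'
#' @param table Variant data.frame (long format).
#' @return List with `correlation` (sample x sample matrix, `NA` where a
#'   pair shares < 2 defined MAFs or a vector is constant), `hclust`,
#'   and `order` (dendrogram leaf order as sample ids; `NULL` when fewer
#'   than 2 complete variants exist).
#' @export
sample_similarity <- function(table) {
  if (!"maf" %in% names(table)) table <- add_maf(table)
  samples <- sort(unique(table$sample_id))
  if (length(samples) < 2L) stop("need at least 2 samples")
  m <- matrix(NA_real_, nrow = length(unique(table$variant_id)),
              ncol = length(samples),
              dimnames = list(unique(table$variant_id), samples))
  m[cbind(match(table$variant_id, rownames(m)),
          match(table$sample_id, samples))] <- table$maf
  cors <- suppressWarnings(
    stats::cor(m, use = "pairwise.complete.obs", method = "pearson"))
  n_shared <- crossprod(!is.na(m))
  cors[n_shared < 2] <- NA_real_
  complete <- m[stats::complete.cases(m), , drop = FALSE]
  hc <- NULL
  ord <- NULL
  if (nrow(complete) >= 2L) {
    hc <- stats::hclust(stats::dist(t(complete), method = "euclidean"),
                        method = "complete")
    ord <- hc$labels[hc$order]
  }
  list(correlation = cors, hclust = hc, order = ord)
}
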