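# Clonal-architecture statistics computed from a CountMatrix and a
# sample sheet: dominant barcodes, Shannon diversity, seeding clones,
# tumor-initiating-cell frequency, overlap and distribution summaries.

#' Dominant barcodes of a sample
#'
#' Sorts barcodes by CPM descending (ties broken by barcode id, stable)
#' and returns the smallest prefix whose cumulative CPM reaches
#' `threshold` of the total — the "top 95%" barcodes by default. With
#' `include_crossing = FALSE` the barcode that crosses the threshold is
#' excluded (but at least one barcode is always returned).
#'
#' @param cpm_column Named numeric vector of per-barcode CPM (raw counts
#'   work identically since only proportions matter).
#' @param threshold Cumulative-abundance fraction (default 0.95).
#' @param include_crossing Include the threshold-crossing barcode.
#' @return Character vector of dominant barcode ids, in descending
#'   abundance order.
#' @export
dominant_set <- function(cpm_column, threshold = 0.95,
                         include_crossing = TRUE) {
  x <- cpm_column[cpm_column > 0]
  if (length(x) == 0L) stop("empty sample: no positive abundances")
  stopifnot(threshold > 0, threshold <= 1)
  ord <- order(-x, names(x), method = "radix")
  x <- x[ord]
  cum <- cumsum(x)
  target <- threshold * sum(x)
  k <- which(cum >= target - 1e-9)[1L]
  if (!include_crossing) k <- max(1L, k - 1L)
  names(x)[seq_len(k)]
}

#' Shannon diversity of a barcode count vector (nats)
#'
#' `H = -sum(p_i * log(p_i))` over barcodes with positive counts, with
#' `p_i` the count proportions; natural-log units.
#'
#' @param counts_column Named numeric vector of per-barcode counts.
#' @return Shannon index in nats.
#' @export
shannon_diversity <- function(counts_column) {
  total <- sum(counts_column)
  if (total <= 0) stop("cannot compute diversity of an empty sample")
  p <- counts_column[counts_column > 0] / total
  -sum(p * log(p))
}

#' Seeding clones of a metastasis
#'
#' A seeding clone is any barcode detected (count at or above
#' `min_count`, default 1) in both the metastasis and its matched MFP
#' tumor. Barcodes are only comparable within a mouse; if both mouse
#' labels are supplied and differ the comparison is refused.
#'
#' @param met_counts,mfp_counts Named count vectors for the metastasis
#'   and its matched MFP tumor.
#' @param met_mouse,mfp_mouse Optional mouse labels for the two samples.
#' @param min_count Detection floor (default 1 read).
#' @return Character vector of seeding barcode ids.
#' @export
seeding_clones <- function(met_counts, mfp_counts, met_mouse = NULL,
                           mfp_mouse = NULL, min_count = 1) {
  if (!is.null(met_mouse) && !is.null(mfp_mouse) &&
      !identical(met_mouse, mfp_mouse)) {
    stop("refusing cross-mouse comparison: barcodes are not comparable ",
         "between mice (", met_mouse, " vs ", mfp_mouse, ")")
  }
  met <- names(met_counts)[met_counts >= min_count]
  mfp <- names(mfp_counts)[mfp_counts >= min_count]
  intersect(met, mfp)
}

#' Tumor-initiating cell frequency
#'
#' Percentage of reference (pre-implantation) barcodes detected in the
#' grown tumor: `100 * tumor_unique / reference_unique`. Values above
#' 100% are reported with a warning rather than refused.
#'
#' @param tumor_unique Unique barcodes detected in the tumor.
#' @param reference_unique Unique barcodes in the reference cell pellet.
#' @return Frequency in percent.
#' @export
tic_frequency <- function(tumor_unique, reference_unique) {
  if (reference_unique == 0) stop("reference barcode count is zero")
  pct <- 100 * tumor_unique / reference_unique
  if (pct > 100) warning("TIC frequency exceeds 100%: tumor has more ",
                         "unique barcodes than the reference")
  pct
}

#' Jaccard overlap index of two barcode sets
#'
#' `|A n B| / |A u B|`; two empty sets give 0 with a warning.
#'
#' @param set_a,set_b Character vectors (treated as sets).
#' @return Overlap index in `[0, 1]`.
#' @export
jaccard_index <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  u <- length(union(set_a, set_b))
  if (u == 0L) {
    warning("Jaccard index of two empty sets; returning 0")
    return(0)
  }
  length(intersect(set_a, set_b)) / u
}

#' Two-tailed t-test between two groups of per-sample statistics
#'
#' Welch's unequal-variance test by default (`var_equal = TRUE` gives the
#' pooled-variance Student test). Degenerate zero-variance inputs return
#' t = 0, p = 1 when the means agree and p = 0 otherwise.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Assume equal variances.
#' @return List with `statistic` and `p.value`.
#' @export
group_compare <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 values")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(list(statistic = 0, p.value = 1))
    }
    return(list(statistic = Inf, p.value = 0))
  }
  tt <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(statistic = unname(tt$statistic), p.value = tt$p.value)
}

#' Log-abundance distribution and per-mouse maximum CPM
#'
#' `barcode_density_summary` histograms `log10(CPM)` over a sample's
#' dominant barcodes. `max_cpm_by_mouse` reports, per mouse, the maximum
#' CPM each barcode attains across that mouse's samples.
#'
#' @param cpm_column Named CPM vector for one sample.
#' @param threshold Dominance threshold passed to [dominant_set()]; use
#'   `NULL` to include all detected barcodes.
#' @param breaks Passed to [graphics::hist()].
#' @return For `barcode_density_summary`, a list with `log10_cpm`,
#'   `breaks`, `counts`, `mids`.
#' @export
barcode_density_summary <- function(cpm_column, threshold = 0.95,
                                    breaks = "Sturges") {
  if (length(cpm_column) == 0L) stop("empty CPM vector")
  keep <- if (is.null(threshold)) {
    names(cpm_column)[cpm_column > 0]
  } else {
    dominant_set(cpm_column, threshold)
  }
  lx <- log10(cpm_column[keep])
  h <- graphics::hist(lx, breaks = breaks, plot = FALSE)
  list(log10_cpm = lx, breaks = h$breaks, counts = h$counts,
       mids = h$mids)
}

#' @rdname barcode_density_summary
#' @param cm A `CountMatrix`.
#' @param meta Sample sheet data.frame (`sample_id`, `mouse`, `site`,
#'   `lesion`).
#' @return For `max_cpm_by_mouse`, a named list (one element per mouse)
#'   of per-barcode maximum CPM across that mouse's samples, restricted
#'   to barcodes detected in the mouse.
#' @export
max_cpm_by_mouse <- function(cm, meta) {
  stopifnot(inherits(cm, "CountMatrix"))
  out <- list()
  for (m in unique(meta$mouse)) {
    sids <- meta$sample_id[meta$mouse == m]
    sub <- cm$cpm[, intersect(sids, cm$samples), drop = FALSE]
    mx <- apply(sub, 1L, max)
    out[[m]] <- mx[mx > 0]
  }
  out
}

#' Full clonal-architecture report
#'
#' Computes, from a `CountMatrix` and its sample sheet: per-sample unique
#' and dominant barcode counts plus Shannon diversity; per-metastasis
#' seeding-clone counts, percent-dominant-of-MFP, percent-seeding-of-MFP
#' (both relative to the unique barcodes of the matched MFP tumor), and
#' the Jaccard index between the metastasis' and MFP's dominant sets; and
#' the per-mouse maximum-CPM table. Every metastasis sample's mouse must
#' have exactly one MFP sample, otherwise the comparison is refused.
#'
#' @param cm A `CountMatrix`.
#' @param meta Sample sheet data.frame (`sample_id`, `mouse`, `site`,
#'   `lesion`); sites from `{MFP, lung, liver, brain, reference}`.
#' @param threshold Dominance threshold (default 0.95).
#' @param min_count Detection floor for "detected" (default 1 read).
#' @return Object of class `ClonalReport`: list with data.frames
#'   `per_sample` and `per_metastasis`, plus `max_cpm` (per mouse) and
#'   `dominant_sets` (per sample).
#' @export
clonal_report <- function(cm, meta, threshold = 0.95, min_count = 1) {
  stopifnot(inherits(cm, "CountMatrix"))
  need <- c("sample_id", "mouse", "site", "lesion")
  if (!all(need %in% names(meta))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample ids")
  meta <- meta[meta$sample_id %in% cm$samples, , drop = FALSE]

  doms <- list()
  per_sample <- data.frame(
    sample_id = meta$sample_id, mouse = meta$mouse, site = meta$site,
    n_unique_barcodes = NA_integer_, n_dominant = NA_integer_,
    shannon_nats = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(meta))) {
    sid <- meta$sample_id[i]
    cnt <- cm$counts[, sid]
    per_sample$n_unique_barcodes[i] <- sum(cnt >= min_count)
    if (sum(cnt) > 0) {
      doms[[sid]] <- dominant_set(cm$cpm[, sid], threshold)
      per_sample$n_dominant[i] <- length(doms[[sid]])
      per_sample$shannon_nats[i] <- shannon_diversity(cnt)
    }
  }

  met_rows <- which(meta$site %in% c("lung", "liver", "brain"))
  per_met <- data.frame(
    sample_id = meta$sample_id[met_rows],
    mouse = meta$mouse[met_rows], site = meta$site[met_rows],
    n_seeding = NA_integer_, pct_dominant_of_mfp = NA_real_,
    pct_seeding_of_mfp = NA_real_, jaccard_vs_mfp = NA_real_,
    stringsAsFactors = FALSE)
  for (i in seq_along(met_rows)) {
    r <- met_rows[i]
    mouse <- meta$mouse[r]
    mfp_sid <- meta$sample_id[meta$mouse == mouse & meta$site == "MFP"]
    if (length(mfp_sid) != 1L) {
      stop(sprintf(
        "mouse %s has %d MFP samples; metastasis comparisons need exactly 1",
        mouse, length(mfp_sid)))
    }
    sid <- meta$sample_id[r]
    seeding <- seeding_clones(cm$counts[, sid], cm$counts[, mfp_sid],
                              met_mouse = mouse, mfp_mouse = mouse,
                              min_count = min_count)
    mfp_unique <- sum(cm$counts[, mfp_sid] >= min_count)
    per_met$n_seeding[i] <- length(seeding)
    per_met$pct_dominant_of_mfp[i] <-
      100 * length(doms[[sid]]) / mfp_unique
    per_met$pct_seeding_of_mfp[i] <- 100 * length(seeding) / mfp_unique
    per_met$jaccard_vs_mfp[i] <- jaccard_index(doms[[sid]],
                                               doms[[mfp_sid]])
  }

  structure(list(per_sample = per_sample, per_metastasis = per_met,
                 max_cpm = max_cpm_by_mouse(cm, meta),
                 dominant_sets = doms, threshold = threshold),
            class = "ClonalReport")
}

#' @export
print.ClonalReport <- function(x, ...) {
  cat(sprintf("ClonalReport: %d samples, %d metastases (threshold %.2f)\n",
              nrow(x$per_sample), nrow(x$per_metastasis), x$threshold))
  print(utils::head(x$per_sample, 10L))
  invisible(x)
}
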