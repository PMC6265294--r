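test_that("dominant sets follow the cumulative-abundance prefix rule", {
  shares <- c(a = 0.50, b = 0.30, c = 0.15, d = 0.05) * 1e6
  expect_equal(dominant_set(shares, 0.95), c("a", "b", "c"))
  expect_equal(dominant_set(c(only = 42), 0.95), "only")

  uniform <- setNames(rep(1e4, 100), sprintf("b%03d", 1:100))
  expect_length(dominant_set(uniform, 0.95), 95)
  # Ties broken by barcode id ascending.
  expect_equal(dominant_set(uniform, 0.95)[1:3], c("b001", "b002", "b003"))

  # threshold 1 returns every detected barcode; monotone in threshold.
  set.seed(5)
  for (rep in 1:20) {
    x <- setNames(rexp(30), sprintf("x%02d", 1:30))
    expect_setequal(dominant_set(x, 1), names(x))
    sizes <- vapply(c(0.5, 0.7, 0.9, 0.95, 0.99, 1),
                    function(th) length(dominant_set(x, th)), numeric(1))
    expect_true(all(diff(sizes) >= 0))
    # Brute-force prefix oracle: the returned prefix reaches the target
    # and the next-smaller prefix does not.
    ds <- dominant_set(x, 0.9)
    expect_gte(sum(x[ds]), 0.9 * sum(x) - 1e-9)
    if (length(ds) > 1) {
      expect_lt(sum(x[ds[-length(ds)]]), 0.9 * sum(x))
    }
  }
  expect_error(dominant_set(c(a = 0, b = 0)), "empty sample")
  expect_length(dominant_set(shares, 0.95, include_crossing = FALSE), 2)
})

test_that("Shannon diversity matches closed forms and is relabeling-invariant", {
  expect_equal(shannon_diversity(rep(25, 4)), log(4))
  expect_equal(shannon_diversity(c(lone = 99)), 0)
  expect_equal(shannon_diversity(c(2, 1, 1) * 10), 1.0397, tolerance = 1e-4)
  expect_error(shannon_diversity(c(0, 0)), "empty")

  set.seed(7)
  x <- rpois(50, 20) + 1
  expect_equal(shannon_diversity(x), shannon_diversity(rev(x)))
  expect_lte(shannon_diversity(x), log(length(x)))
  expect_equal(shannon_diversity(rep(7, 50)), log(50))
})

test_that("seeding clones are the detected intersection within a mouse", {
  expect_length(seeding_clones(c(a = 3), c(b = 5)), 0)
  expect_equal(seeding_clones(c(a = 1, b = 500), c(b = 2, c = 9)), "b")
  met <- c(x = 1, y = 2)
  mfp <- c(x = 9, y = 1, z = 4)
  expect_setequal(seeding_clones(met, mfp), names(met))
  expect_error(seeding_clones(met, mfp, met_mouse = "A", mfp_mouse = "B"),
               "cross-mouse")
  # Detection floor.
  expect_equal(seeding_clones(c(a = 1, b = 5), c(a = 1, b = 5),
                              min_count = 2), "b")
})

test_that("TIC frequency is the reference-normalized percentage", {
  expect_equal(tic_frequency(5, 5), 100)
  expect_error(tic_frequency(10, 0), "zero")
  expect_warning(pct <- tic_frequency(20, 10), "exceeds 100")
  expect_equal(pct, 200)
})

test_that("Jaccard index handles identical, disjoint and partial overlap", {
  expect_equal(jaccard_index(c("a", "b"), c("a", "b")), 1)
  expect_equal(jaccard_index(c("a"), c("b")), 0)
  expect_equal(jaccard_index(c("a", "b", "c"), c("b", "c", "d")), 0.5)
  expect_warning(j0 <- jaccard_index(character(0), character(0)), "empty")
  expect_equal(j0, 0)
})

test_that("group comparison is a two-tailed t-test with Welch default", {
  same <- group_compare(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  # Hand Welch oracle: a = (1,2,3), b = a + 10 gives
  # t = -10 / sqrt(1/3 + 1/3), df = 4.
  shifted <- group_compare(c(1, 2, 3), c(11, 12, 13))
  t_hand <- -10 / sqrt(1 / 3 + 1 / 3)
  expect_equal(shifted$statistic, t_hand, tolerance = 1e-12)
  expect_equal(shifted$p.value, 2 * pt(t_hand, df = 4), tolerance = 1e-12)
  expect_lt(shifted$p.value, 0.01)

  expect_error(group_compare(1, c(1, 2)), "at least 2")

  # Type-I error control under the null, alpha 0.05.
  set.seed(99)
  rejections <- vapply(1:10000, function(i) {
    group_compare(rnorm(5), rnorm(5))$p.value < 0.05
  }, logical(1))
  expect_lt(abs(mean(rejections) - 0.05), 0.01)
})

test_that("density summaries and max-CPM tables reflect the abundance structure", {
  one <- barcode_density_summary(c(b = 1e6), threshold = NULL)
  expect_equal(unname(one$log10_cpm), 6)
  expect_equal(sum(one$counts), 1)

  cpmm <- rbind(b1 = c(10, 0, 3000), b2 = c(5, 5, 5))
  colnames(cpmm) <- c("s1", "s2", "s3")
  cm <- structure(list(cpm = cpmm, counts = cpmm,
                       samples = colnames(cpmm)),
                  class = "CountMatrix")
  meta <- data.frame(sample_id = colnames(cpmm), mouse = "A",
                     site = c("MFP", "lung", "lung"), lesion = c("MFP", "l1", "l2"))
  mx <- max_cpm_by_mouse(cm, meta)
  expect_equal(unname(mx$A["b1"]), 3000)

  # Simulated mouse with strong dominance: dominant clones separate from
  # the rest of the lesion by more than one log10 unit of max CPM. The
  # separation is a prediction of the dominance model at moderate
  # clone-size dispersion; at very heavy-tailed clone sizes the two
  # modes can overlap because the boost multiplies each dominant
  # clone's own (low) MFP abundance.
  lib <- make_half_library(80, 18, 3, seed = 17)
  sp <- sim_params(n_cells = 30000, mice = list(A = c("lung", "liver")),
                   seeders_per_lesion = 100, n_dominant = 5,
                   dominance_factor = 500, nb_dispersion = 5,
                   reads_per_sample = 5e4,
                   error_rate = 0, junk_fraction = 0)
  sim <- simulate_experiment(sp, lib, seed = 23)
  cmx <- count_pairs(sim$reads, lib)
  dom <- sim$truth$A$dominant_set
  lesions <- grep("MFP", colnames(cmx$cpm), invert = TRUE, value = TRUE)
  mets_meta <- sim$samples[sim$samples$sample_id %in% lesions |
                             sim$samples$site != "MFP", ]
  mx2 <- max_cpm_by_mouse(
    structure(list(cpm = cmx$cpm[, lesions, drop = FALSE],
                   counts = cmx$counts[, lesions, drop = FALSE],
                   samples = lesions), class = "CountMatrix"),
    sim$samples[sim$samples$sample_id %in% lesions, ])
  vals <- mx2$A
  expect_true(all(dom %in% names(vals)))
  gap <- min(log10(vals[dom])) - max(log10(vals[setdiff(names(vals), dom)]))
  expect_gt(gap, 1)
})

test_that("the clonal report ties metrics to matched MFP tumors", {
  lib <- make_half_library(50, 18, 3, seed = 31)
  sp <- sim_params(n_cells = 5000, mice = list(A = c("lung", "liver"),
                                               B = "lung"),
                   seeders_per_lesion = 15, n_dominant = 3,
                   reads_per_sample = 1e4, error_rate = 0,
                   junk_fraction = 0)
  sim <- simulate_experiment(sp, lib, seed = 37)
  cm <- count_pairs(sim$reads, lib)
  rep <- clonal_report(cm, sim$samples)

  expect_true(all(rep$per_sample$n_dominant <=
                    rep$per_sample$n_unique_barcodes))
  expect_true(all(rep$per_sample$shannon_nats >= 0))
  expect_true(all(rep$per_metastasis$jaccard_vs_mfp >= 0 &
                    rep$per_metastasis$jaccard_vs_mfp <= 1))
  # seeding_clones(met, MFP) contains dominant(met) intersected with
  # barcodes detected in the MFP.
  for (i in seq_len(nrow(rep$per_metastasis))) {
    sid <- rep$per_metastasis$sample_id[i]
    mouse <- rep$per_metastasis$mouse[i]
    mfp <- paste0(mouse, "_MFP")
    seen <- seeding_clones(cm$counts[, sid], cm$counts[, mfp])
    dom_in_mfp <- intersect(rep$dominant_sets[[sid]],
                            rownames(cm$counts)[cm$counts[, mfp] > 0])
    expect_true(all(dom_in_mfp %in% seen))
  }

  # A mouse with two MFP samples is refused.
  bad_meta <- sim$samples
  bad_meta$site[bad_meta$sample_id == "A_lung1"] <- "MFP"
  expect_error(clonal_report(cm, bad_meta), "exactly 1")
})
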