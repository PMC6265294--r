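test_that("WES consensus filters eliminate the published rule violations", {
  maf <- matrix(0.3, 4, 3,
                dimnames = list(paste0("v", 1:4), paste0("s", 1:3)))
  tab <- variant_table_from_maf(maf, depth = 100, platform = "WES")
  # v1 violates the single-caller rule, v2 sits in the population
  # database, v3 is silent; v4 passes everything.
  tab$n_callers[tab$variant_id == "v1"] <- 1
  tab$in_population_db[tab$variant_id == "v2"] <- TRUE
  tab$is_silent[tab$variant_id == "v3"] <- TRUE
  res <- consensus_filter(tab, "WES")
  expect_setequal(unique(res$table$variant_id), "v4")
  expect_equal(res$log$single_caller, 1)
  expect_equal(res$log$population_db, 1)
  expect_equal(res$log$silent_or_noncoding, 1)
  expect_equal(res$log$n_dropped_variants, 3)

  # Coverage rules: eliminated only when violated in ALL samples.
  low <- variant_table_from_maf(
    matrix(0.5, 2, 2, dimnames = list(c("lo", "hi"), c("s1", "s2"))),
    depth = 20, platform = "WES")
  low[low$variant_id == "hi" & low$sample_id == "s2",
      c("ref_reads", "alt_reads")] <- c(50, 50)
  res2 <- consensus_filter(low, "WES")
  expect_setequal(unique(res2$table$variant_id), "hi")

  # Idempotence.
  res3 <- consensus_filter(res$table, "WES")
  expect_equal(res3$table$variant_id, res$table$variant_id)
  expect_equal(res3$log$n_dropped_variants, 0)

  expect_error(consensus_filter(tab[, setdiff(names(tab), "germline_vaf")],
                                "WES"), "germline_vaf")
})

test_that("targeted modes set per-sample detection status", {
  maf <- matrix(c(0.02, 0.5), 1, 2,
                dimnames = list("v1", c("s1", "s2")))
  tab <- variant_table_from_maf(maf, depth = 100)
  res <- consensus_filter(tab, "targeted")
  st <- setNames(res$table$detected, res$table$sample_id)
  expect_false(st[["s1"]])   # 2 mutant reads < 3
  expect_true(st[["s2"]])    # 50 mutant reads

  # Barcoded targeted mode additionally requires 100x total coverage.
  res_bc <- consensus_filter(tab, "targeted_barcoded")
  expect_equal(unname(res_bc$table$detected),
               unname(res$table$detected))
  thin <- variant_table_from_maf(matrix(0.5, 1, 1,
                                        dimnames = list("v1", "s1")),
                                 depth = 50)
  expect_false(consensus_filter(thin, "targeted_barcoded")$table$detected)
  expect_true(consensus_filter(thin, "targeted")$table$detected)
})

test_that("delta-MAF classification applies the 0.15 / 0.05 thresholds", {
  mets <- paste0("M", 1:3)
  pris <- paste0("P", 1:3)
  maf <- rbind(
    flat = rep(0.4, 6),
    up = c(0.10, 0.12, 0.11, 0.60, 0.62, 0.58),
    small = c(0.10, 0.11, 0.10, 0.20, 0.21, 0.19))
  colnames(maf) <- c(pris, mets)
  tab <- variant_table_from_maf(maf, depth = 1000)
  res <- delta_maf(tab, group_met = mets, group_primary = pris)
  res <- res[match(c("flat", "up", "small"), res$variant_id), ]

  expect_equal(res$delta_maf[1], 0)
  expect_equal(res$class[1], "neutral")

  expect_equal(res$delta_maf[2], 0.49, tolerance = 0.01)
  expect_equal(res$class[2], "enriched")
  # Hand Welch oracle for the enriched row.
  met_v <- maf["up", mets]; pri_v <- maf["up", pris]
  t_hand <- (mean(met_v) - mean(pri_v)) /
    sqrt(var(met_v) / 3 + var(pri_v) / 3)
  expect_equal(res$t[2], t_hand, tolerance = 1e-6)
  expect_lt(res$p[2], 0.001)

  # Below the effect-size cut: neutral despite a small p-value.
  expect_lt(res$p[3], 0.05)
  expect_equal(res$class[3], "neutral")

  # Antisymmetry under group swap.
  swapped <- delta_maf(tab, group_met = pris, group_primary = mets)
  swapped <- swapped[match(res$variant_id, swapped$variant_id), ]
  expect_equal(swapped$delta_maf, -res$delta_maf)
  expect_equal(swapped$p, res$p)
  expect_equal(swapped$class[2], "depleted")

  # Zero-coverage MAFs are undefined and can render a variant untestable.
  tab0 <- tab[tab$variant_id == "flat", ]
  tab0[tab0$sample_id %in% c("M1", "M2"),
       c("ref_reads", "alt_reads")] <- 0
  res0 <- delta_maf(tab0, group_met = mets, group_primary = pris)
  expect_equal(res0$class, "untestable")
})

test_that("de novo candidates require clean MFPs and a single mouse", {
  meta <- data.frame(
    sample_id = c("MFP1", "MFP2", "m1_lu", "m2_lu"),
    mouse = c("m0", "m0", "m1", "m2"),
    site = c("MFP", "MFP", "lung", "lung"), stringsAsFactors = FALSE)
  base <- expand.grid(
    variant_id = c("good", "two_mice", "absent", "dirty_mfp"),
    sample_id = meta$sample_id, stringsAsFactors = FALSE)
  base$ref_reads <- 500
  base$alt_reads <- 0
  base$platform <- "targeted"
  # WES rows for the MFPs.
  wes <- base[base$sample_id %in% c("MFP1", "MFP2"), ]
  wes$platform <- "WES"
  tab <- rbind(base, wes)

  put <- function(tab, v, s, alt, platform = "targeted") {
    i <- tab$variant_id == v & tab$sample_id == s & tab$platform == platform
    tab$alt_reads[i] <- alt
    tab
  }
  tab <- put(tab, "good", "m1_lu", 40)
  tab <- put(tab, "good", "MFP1", 6)        # < 7 targeted reads: non-mutant
  tab <- put(tab, "two_mice", "m1_lu", 40)
  tab <- put(tab, "two_mice", "m2_lu", 40)
  tab <- put(tab, "dirty_mfp", "m1_lu", 40)
  tab <- put(tab, "dirty_mfp", "MFP2", 9)   # >= 7: mutant MFP

  cand <- de_novo_candidates(tab, meta)
  expect_equal(cand, "good")

  expect_error(de_novo_candidates(tab[, setdiff(names(tab), "platform")],
                                  meta), "platform")
})

test_that("the co-occurrence filter flags correlated pairs and applies the 1% cut", {
  cooc <- data.frame(
    mut_a = c("a1", "a2", "a3"), mut_b = c("b1", "b2", "b3"),
    n_both = c(50, 1, 5), n_only_a = c(0, 9, 5), n_only_b = c(0, 9, 5),
    n_neither = c(50, 81, 985))
  res <- repeat_artifact_filter(cooc)
  # Perfect correlation at 50% of reads: flagged and discarded.
  expect_true(res$pairs$flagged[1])
  expect_true(res$pairs$discarded[1])
  expect_setequal(res$discarded_mutations, c("a1", "b1"))
  # Exactly-independent table: expected equals observed, not flagged.
  expect_false(res$pairs$flagged[2])
  # Strongly correlated but below the 1% read-fraction cut: retained.
  expect_true(res$pairs$flagged[3])
  expect_false(res$pairs$discarded[3])

  # Zero-margin pair is untestable, not an error.
  z <- repeat_artifact_filter(data.frame(
    mut_a = "a", mut_b = "b", n_both = 0, n_only_a = 0, n_only_b = 10,
    n_neither = 90))
  expect_true(z$pairs$untestable[1])
  expect_false(z$pairs$flagged[1])
})

test_that("qPCR human fraction follows the delta-Ct partition formula", {
  expect_equal(human_fraction(3, 3), 50)
  expect_equal(human_fraction(1, 2), 100 * 0.5 / 0.75)
  expect_equal(human_fraction(Inf, 2), 0)
  expect_equal(human_fraction(2, Inf), 100)
})

test_that("sample similarity reproduces hand-computed correlation and linkage", {
  maf <- rbind(v1 = c(0.1, 0.1, 0.9), v2 = c(0.5, 0.5, 0.1),
               v3 = c(0.9, 0.9, 0.2))
  colnames(maf) <- c("A", "B", "C")
  tab <- variant_table_from_maf(maf, depth = 1000)
  sim <- sample_similarity(tab)
  expect_equal(sim$correlation["A", "B"], 1)
  # A and B are identical: the first merge joins them at height 0.
  first_merge <- sim$hclust$labels[-sim$hclust$merge[1, ]]
  expect_setequal(first_merge, c("A", "B"))
  expect_equal(sim$hclust$height[1], 0)
  # Identical samples stay adjacent in the leaf order.
  expect_equal(abs(diff(match(c("A", "B"), sim$order))), 1)

  anti_m <- rbind(v1 = c(0, 1), v2 = c(1, 0)) * 0.5
  colnames(anti_m) <- c("X", "Y")
  s2 <- sample_similarity(variant_table_from_maf(anti_m, depth = 1000))
  expect_equal(s2$correlation[1, 2], -1)

  # Constant MAF vector: correlation undefined, flagged as NA.
  const_m <- rbind(v1 = c(0.5, 0.2), v2 = c(0.5, 0.8))
  colnames(const_m) <- c("X", "Y")
  s3 <- sample_similarity(variant_table_from_maf(const_m, depth = 1000))
  expect_true(is.na(s3$correlation[1, 2]))
})
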