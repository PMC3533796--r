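test_that("top_candidates orders by p with deterministic tie-breaking", {
  scan <- data.table::data.table(
    chrom = c("2L", "2L", "3R", "X"), pos = c(10L, 20L, 5L, 7L),
    contrast = "B-M", statistic = 1, p = c(0.5, 0.001, 0.01, 0.2),
    k_used = 3L)
  top <- top_candidates(scan, 3)
  expect_equal(top$p, c(0.001, 0.01, 0.2))
  expect_equal(top$rank, 1:3)
  # ties broken by (chrom, pos)
  scan2 <- data.table::data.table(
    chrom = c("3R", "2L"), pos = c(1L, 9L), contrast = "B-M",
    statistic = 1, p = c(0.05, 0.05), k_used = 3L)
  expect_equal(top_candidates(scan2, 1)$chrom, "2L")
  expect_error(top_candidates(scan, 10), "defined p-values")
})

test_that("selected-allele orientation follows the mean change", {
  design <- two_point_design(k = 3)
  freqs <- rbind(c(0.2, 0.2, 0.2, 0.5, 0.5, 0.5),   # minor rises
                 c(0.5, 0.5, 0.5, 0.2, 0.2, 0.2),   # minor falls
                 c(0.3, 0.3, 0.3, 0.5, 0.5, 0.1))   # mixed, positive mean
  snps <- snp_table_from_freqs(freqs, coverage = 100)
  ori <- orient_selected_allele(snps, design, c("B", "E"))
  expect_equal(ori$selected_allele, c("T", "A", "T"))
  expect_equal(ori$flag, c("ok", "ok", "inconsistent_replicates"))
  expect_equal(ori$mean_afc[1], 0.3, tolerance = 1e-12)
  expect_equal(ori$mean_afc[2], 0.3, tolerance = 1e-12)
})

test_that("interval AFC telescopes exactly across time points", {
  design <- three_point_design(k = 3)
  set.seed(41)
  freqs <- matrix(runif(9 * 20), 20, 9)
  snps <- snp_table_from_freqs(freqs, coverage = 200)
  traj <- trajectory_table(snps, design)
  bm <- interval_afc(traj, "B", "M")
  me <- interval_afc(traj, "M", "E")
  be <- interval_afc(traj, "B", "E")
  m <- merge(merge(bm, me, by = c("chrom", "pos", "replicate")),
             be, by = c("chrom", "pos", "replicate"))
  expect_equal(m$afc.x + m$afc.y, m$afc, tolerance = 1e-12)
  expect_error(interval_afc(traj, "B", "Z"), "time point")
})

test_that("classification rules and partitioning", {
  # frequencies 0.1, 0.5, 0.5 -> rise 0.4, late 0: plateau
  # frequencies 0.1, 0.3, 0.6 -> rise 0.2, late 0.3: continuous
  lab <- classify_trajectories(rise = c(0.4, 0.2), late = c(0, 0.3),
                               rise_min = 0.2, flat_max = 0.05)
  expect_equal(as.character(lab), c("plateau", "continuous"))
  expect_error(classify_trajectories(0.1, 0.1, rise_min = -1, flat_max = 0.1),
               "positive")
  expect_error(classify_trajectories(0.1, 0.1, rise_min = 0.1), "null_late")
  # labels partition any candidate set
  set.seed(43)
  rise <- runif(500, -0.2, 0.8); late <- runif(500, -0.3, 0.6)
  lab2 <- classify_trajectories(rise, late, null_late = rnorm(1000, 0, 0.07))
  expect_equal(sum(table(lab2)), 500)
  expect_true(all(as.character(lab2) %in% c("plateau", "continuous", "other")))
})

test_that("fixation fractions at both reporting thresholds", {
  f <- c(0.995, 0.5, 0.7, 0.2)
  expect_equal(fixation_fraction(f, 0.99), 0.25)
  expect_equal(fixation_fraction(f, 0.90, inclusive = FALSE), 0.25)
  expect_equal(fixation_fraction(rep(1, 5), 0.99), 1)
  expect_error(fixation_fraction(f, 0), "threshold")
  # neutral drifted candidates essentially never fix by generation 37
  set.seed(47)
  p <- wf_trajectory(runif(2000, 0.05, 0.5), 200, 37)
  expect_lt(fixation_fraction(p, 0.99), 0.02)
})

test_that("candidate overlap reports count and fraction", {
  a <- data.frame(chrom = "2L", pos = 1:2000)
  b <- data.frame(chrom = "2L", pos = 1554:3553)
  ov <- candidate_overlap(a, b)
  expect_equal(ov$count, 447L)
  expect_equal(ov$fraction, 447 / 2000)
  expect_equal(round(100 * ov$fraction), 22)
  expect_equal(candidate_overlap(a, a)$fraction, 1)
  expect_equal(candidate_overlap(a, data.frame(chrom = "3R", pos = 1:10))$count, 0)
})

test_that("flanking decay bins by distance and excludes the candidates", {
  cand <- data.frame(chrom = "2L", pos = 10000L)
  snp_afc <- data.table::data.table(
    chrom = "2L",
    pos = c(10000L, 10130L, 9900L, 10100L, 10550L, 30000L),
    afc = c(0.9, 0.3, 0.1, 0.2, 0.4, 0.05))
  out <- flanking_decay(cand, snp_afc, bin_width = 100, span = 1000,
                        control_offset = 5000)
  cand_bins <- out[out$set == "candidate", ]
  # SNP 130 bp away falls in the second bin; candidate itself excluded
  expect_true(2L %in% cand_bins$bin)
  expect_equal(cand_bins$median_afc[cand_bins$bin == 2L], 0.3)
  # first bin holds the two SNPs at distance 100
  expect_equal(cand_bins$n_snps[cand_bins$bin == 1L], 2L)
  expect_equal(cand_bins$median_afc[cand_bins$bin == 1L], 0.15)
  # bin 6 holds the SNP at 550
  expect_equal(cand_bins$median_afc[cand_bins$bin == 6L], 0.4)
  expect_false(0.9 %in% cand_bins$median_afc)
  # control centered at 5000: no SNPs within span -> no control rows there
  expect_error(flanking_decay(cand, snp_afc, bin_width = 200, span = 100),
               "span")
})

test_that("selected trajectories flip major-oriented SNPs", {
  design <- two_point_design(k = 2)
  freqs <- rbind(c(0.2, 0.2, 0.5, 0.5),
                 c(0.5, 0.5, 0.2, 0.2))
  snps <- snp_table_from_freqs(freqs, coverage = 100)
  ori <- orient_selected_allele(snps, design, c("B", "E"))
  traj <- selected_trajectories(snps, design, ori)
  # SNP 2's selected allele is the major one: frequencies flipped
  f2 <- traj[traj$pos == 2L & traj$timepoint == "B", freq]
  expect_equal(f2, c(0.5, 0.5))
  f2e <- traj[traj$pos == 2L & traj$timepoint == "E", freq]
  expect_equal(f2e, c(0.8, 0.8))
})
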