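test_that("wf_trajectory absorbs at the boundaries and validates inputs", {
  expect_equal(wf_trajectory(c(0, 1), 200, 50), c(0, 1))
  expect_error(wf_trajectory(0.5, 1, 10), "N")
  expect_error(wf_trajectory(1.5, 200, 10), "p0")
})

test_that("drift is a martingale with the closed-form variance", {
  set.seed(101)
  n <- 1e5; p0 <- 0.3; N <- 200; t <- 15
  p <- wf_trajectory(rep(p0, n), N, t)
  se_mean <- sd(p) / sqrt(n)
  expect_lt(abs(mean(p) - p0), 3 * se_mean)
  v_exp <- p0 * (1 - p0) * (1 - (1 - 1 / N)^t)
  dev2 <- (p - p0)^2
  se_var <- sd(dev2) / sqrt(n)
  expect_lt(abs(mean(dev2) - v_exp), 3 * se_var)
})

test_that("a neutral allele fixes with probability ~ p0", {
  set.seed(55)
  N <- 20; p0 <- 0.2; n <- 4000
  p <- wf_trajectory(rep(p0, n), N, 50 * N)
  expect_true(all(p %in% c(0, 1)))
  se <- sqrt(p0 * (1 - p0) / n)
  expect_lt(abs(mean(p) - p0), 3 * se)
})

test_that("sample_reads is binomial read sampling", {
  expect_equal(sample_reads(0, 50), 0L)
  expect_equal(sample_reads(1, 50), 50L)
  set.seed(77)
  x <- sample_reads(rep(0.25, 1e5), 60)
  expect_lt(abs(mean(x) - 15), 3 * sd(x) / sqrt(1e5))
  # distributional check against the binomial pmf
  br <- 0:60
  obs <- tabulate(x + 1L, 61)
  pr <- dbinom(br, 60, 0.25)
  keep <- pr * 1e5 >= 5
  grp <- c(sum(obs[!keep & br < 15]), obs[keep], sum(obs[!keep & br >= 15]))
  pgrp <- c(sum(pr[!keep & br < 15]), pr[keep], sum(pr[!keep & br >= 15]))
  gof <- suppressWarnings(chisq.test(grp, p = pgrp))  # tails grouped by hand
  expect_gt(gof$p.value, 0.01)
})

test_that("empirical_threshold is the clamped order statistic", {
  set.seed(3)
  p <- runif(1e5)
  thr <- empirical_threshold(p, 1e-4)   # ceiling gives the 10th smallest
  expect_equal(thr, sort(p)[10])
  p <- runif(100)
  expect_equal(empirical_threshold(p, 1e-5), min(p))
  expect_equal(empirical_threshold(rep(0.2, 50), 0.5), 0.2)
  expect_error(empirical_threshold(p, 0), "top_fraction")
  expect_error(empirical_threshold(p, 1.5), "top_fraction")
})

test_that("empirical_fdr applies the scale and flags empty discovery sets", {
  # sim twice the size of exp -> scale 0.5
  exp_p <- c(0.001, 0.01, 0.5, 0.9)
  sim_p <- c(0.0005, 0.002, rep(0.6, 6))
  r <- empirical_fdr(exp_p, sim_p, threshold = 0.01)
  expect_equal(r$scale, 0.5)
  expect_equal(r$n_sim_below, 2L)
  expect_equal(r$n_exp_below, 2L)
  expect_equal(r$fdr, 2 * 0.5 / 2)
  r0 <- empirical_fdr(c(0.5, 0.9), sim_p, threshold = 1e-4)
  expect_equal(r0$n_exp_below, 0L)
  expect_false(is.na(r0$flag))
  expect_error(empirical_fdr(numeric(), sim_p, 0.1), "empty experimental")
})

test_that("fdr_top_n uses the n-th experimental p-value and self-calibrates", {
  set.seed(21)
  exp_p <- runif(5000)
  sim_p <- runif(5000)
  r <- fdr_top_n(exp_p, sim_p, n = 500)
  expect_equal(r$threshold, sort(exp_p)[500])
  expect_equal(r$n_exp_below, 500L)
  # two independent null sets: fdr ~ 1
  expect_gt(r$fdr, 0.5); expect_lt(r$fdr, 2)
  # strictly smaller experimental p-values: fdr 0
  r0 <- fdr_top_n(runif(3000, 0, 1e-4), runif(3000, 0.5, 1), n = 100)
  expect_equal(r0$fdr, 0)
  expect_error(fdr_top_n(runif(10), sim_p, n = 100), "fewer")
})

test_that("the null experiment is reproducible and collapses to read noise at huge N", {
  design <- two_point_design(k = 3, t = 15)
  p0 <- generate_base_frequencies(500)
  set.seed(5)
  a <- simulate_null_experiment(design, N = 200, p0 = p0,
                                coverage_model = "uniform",
                                contrasts = list(c("B", "E")))
  set.seed(5)
  b <- simulate_null_experiment(design, N = 200, p0 = p0,
                                coverage_model = "uniform",
                                contrasts = list(c("B", "E")))
  expect_identical(a$snps$minor_counts, b$snps$minor_counts)
  expect_identical(a$scans[["B-E"]], b$scans[["B-E"]])

  # N -> infinity: allele-frequency change reduces to binomial read noise
  set.seed(6)
  big <- simulate_null_experiment(design, N = 1e7, p0 = rep(0.5, 2000),
                                  coverage_model = "uniform", filter = FALSE,
                                  contrasts = list(c("B", "E")))
  f <- big$snps$minor_counts / big$snps$coverage
  afc <- rowMeans(f[, 4:6]) - rowMeans(f[, 1:3])
  v_read <- mean(0.5 * 0.5 * rowSums(1 / big$snps$coverage[, 1:6]) / 9)
  expect_lt(abs(var(afc) / v_read - 1), 0.15)
})

test_that("null-vs-null pipelines calibrate the empirical FDR near 1", {
  set.seed(31)
  design <- two_point_design(k = 3, t = 15)
  p0 <- generate_base_frequencies(3e4)
  sim <- simulate_null_experiment(design, N = 200, p0 = p0,
                                  coverage_model = "uniform",
                                  contrasts = list(c("B", "E")))
  exp_ <- simulate_null_experiment(design, N = 200, p0 = p0,
                                   coverage_model = "uniform",
                                   contrasts = list(c("B", "E")))
  sp <- sim$scans[["B-E"]]$p; ep <- exp_$scans[["B-E"]]$p
  thr <- empirical_threshold(sp, 1e-2)
  r <- empirical_fdr(ep, sp, thr)
  expect_gt(r$fdr, 0.5); expect_lt(r$fdr, 2)
  # tail calibration: the fraction of null "experimental" SNPs below the
  # null q-quantile threshold is q, within binomial error
  sp_ok <- sp[!is.na(sp)]; ep_ok <- ep[!is.na(ep)]
  for (q in c(0.001, 0.01, 0.05)) {
    thr <- quantile(sp_ok, q, type = 1)
    frac <- mean(ep_ok <= thr)
    expect_lt(abs(frac - q), 4 * sqrt(q * (1 - q) / length(ep_ok)) + 1e-4)
  }
})
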