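#' Neutral Wright-Fisher allele-frequency trajectory
#'
#' Propagates allele frequencies through `t` generations of binomial drift in
#' a haploid population of constant size `N`: each generation the new count
#' is a Binomial(N, p) draw and the new frequency its proportion. The
#' boundaries 0 and 1 are absorbing.
#'
#' @param p0 starting frequency (vectorized).
#' @param N haploid population size (>= 2).
#' @param t number of generations (>= 0).
#' @return frequency vector after `t` generations.
#' @export
wf_trajectory <- function(p0, N, t) {
  check_number(N, "N", min = 2, integer = TRUE)
  check_number(t, "t", min = 0, integer = TRUE)
  if (any(p0 < 0 | p0 > 1)) stop_param("p0 must be in [0, 1]")
  p <- p0
  for (g in seq_len(t)) p <- rbinom(length(p), N, p) / N
  p
}

#' Binomial read sampling of a pooled allele frequency
#'
#' @param p allele frequency (vectorized).
#' @param coverage read depth (vectorized, recycled).
#' @return integer vector of minor-allele read counts.
#' @export
sample_reads <- function(p, coverage) {
  if (any(p < 0 | p > 1)) stop_param("p must be in [0, 1]")
  if (any(coverage < 0)) stop_param("coverage must be >= 0")
  rbinom(max(length(p), length(coverage)), coverage, p)
}

# draw a (sites x populations) coverage matrix
draw_coverage <- function(n, P, model, cov_range, cov_mean, matched = NULL) {
  switch(model,
    matched = {
      if (is.null(matched)) stop_param(
        "coverage_model = 'matched' needs `base_snps` with coverages for every population")
      if (ncol(matched) != P) stop_param(
        "matched coverages have ", ncol(matched), " populations, design has ", P)
      matched
    },
    uniform = matrix(sample(seq(cov_range[1], cov_range[2]), n * P, TRUE),
                     n, P),
    poisson = matrix(rpois(n * P, cov_mean), n, P),
    stop_param("unknown coverage model: ", model))
}

#' Simulate a coverage-matched neutral null experiment
#'
#' Re-creates the whole experiment under pure drift: starting from the
#' base-population allele frequencies, each replicate's frequency is
#' propagated by [wf_trajectory()] to each of its sequenced generations
#' (sharing the lineage within a replicate), reads are drawn binomially at
#' the design's populations with matched or parametric coverages, the
#' simulated counts are subjected to the same SNP-calling filters as the
#' experimental data, and the requested CMH contrasts are computed.
#'
#' Randomness uses R's global RNG: call `set.seed()` beforehand for a
#' reproducible run; identical seed and configuration give identical output.
#'
#' @param design an [er_design()].
#' @param N haploid Wright-Fisher size; defaults to `design$ne`.
#' @param base_snps optional experimental `snp_table` supplying starting
#'   frequencies (pooled minor counts over base populations) and, under the
#'   matched coverage model, the per-SNP per-population coverages. Starting
#'   frequencies and coverage vectors stay paired SNP-wise, so the
#'   coverage-frequency correlation of the real data is preserved.
#' @param p0 starting frequencies (overrides `base_snps`).
#' @param coverage_model "matched" (reuse `base_snps` coverages), "uniform"
#'   (integer uniform over `cov_range`) or "poisson" (mean `cov_mean`).
#' @param cov_range,cov_mean parameters of the parametric coverage models.
#' @param contrasts list of length-2 time-point contrasts to scan.
#' @param base_label time-point label of the base population.
#' @param filter apply the SNP-calling filters to the simulated counts.
#' @param min_minor_total,min_populations_detected,max_coverage filter
#'   parameters, as in [call_snps()].
#' @return list with `snps` (simulated, filtered `snp_table`), `scans`
#'   (named list of [cmh_scan()] tables), `p0`, `kept` (filter mask over
#'   input loci) and `n_input`.
#' @export
simulate_null_experiment <- function(design, N = NULL, base_snps = NULL,
    p0 = NULL,
    coverage_model = c("matched", "uniform", "poisson"),
    cov_range = c(30L, 64L), cov_mean = 47,
    contrasts = list(c("B", "M"), c("B", "E")),
    base_label = "B", filter = TRUE,
    min_minor_total = 10, min_populations_detected = 2, max_coverage = 500) {
  coverage_model <- match.arg(coverage_model)
  N <- N %||% design$ne
  check_number(N, "N", min = 2, integer = TRUE)
  pops <- design$populations
  P <- nrow(pops)
  if (is.null(p0)) {
    if (is.null(base_snps))
      stop_param("supply either `p0` or `base_snps`")
    bidx <- which(pops$timepoint == base_label)
    if (length(bidx) == 0L) stop_param("no '", base_label,
                                       "' populations in the design")
    p0 <- rowSums(base_snps$minor_counts[, bidx, drop = FALSE]) /
      pmax(rowSums(base_snps$coverage[, bidx, drop = FALSE]), 1L)
  }
  n <- length(p0)
  cov <- draw_coverage(n, P, coverage_model, cov_range, cov_mean,
                       matched = base_snps$coverage)
  # drift: per replicate, walk its sequenced generations in order so that
  # later time points continue the same lineage
  p_true <- matrix(NA_real_, n, P)
  for (r in unique(pops$replicate)) {
    ridx <- which(pops$replicate == r)
    ridx <- ridx[order(pops$generation[ridx])]
    p <- p0; g_now <- 0L
    for (i in ridx) {
      g <- pops$generation[i]
      if (g > g_now) {
        p <- wf_trajectory(p, N, g - g_now)
        g_now <- g
      }
      p_true[, i] <- p
    }
  }
  reads <- matrix(rbinom(n * P, as.vector(cov), as.vector(p_true)), n, P)
  chrom <- if (!is.null(base_snps)) base_snps$chrom else rep("sim", n)
  pos <- if (!is.null(base_snps)) base_snps$pos else seq_len(n)
  snps <- new_snp_table(chrom, pos, rep("A", n), rep("C", n), reads, cov)
  kept <- rep(TRUE, n)
  if (filter) {
    fl <- filter_snp_table(snps, min_minor_total = min_minor_total,
                           max_coverage = max_coverage,
                           min_populations_detected = min_populations_detected)
    snps <- fl$snps; kept <- fl$kept
  }
  scans <- lapply(contrasts, function(ct) cmh_scan(snps, design, ct))
  names(scans) <- vapply(contrasts, contrast_label, "")
  list(snps = snps, scans = scans, p0 = p0, kept = kept, n_input = n)
}

#' Empirical p-value threshold from simulated SNPs
#'
#' The threshold is the `ceiling(top_fraction * n)`-th smallest simulated
#' p-value (at least the smallest), i.e. the highest p-value of the top
#' `top_fraction` of simulated SNPs.
#'
#' @param sim_pvalues p-values from the neutral null simulation.
#' @param top_fraction fraction of simulated SNPs that defines the cutoff
#'   (1e-5 corresponds to the "top 0.001%").
#' @return the p-value threshold.
#' @export
empirical_threshold <- function(sim_pvalues, top_fraction = 1e-5) {
  check_number(top_fraction, "top_fraction")
  if (top_fraction <= 0 || top_fraction > 1)
    stop_param("`top_fraction` must be in (0, 1]")
  sim_pvalues <- sim_pvalues[!is.na(sim_pvalues)]
  if (length(sim_pvalues) == 0L) stop_param("no simulated p-values")
  k <- max(1L, ceiling(top_fraction * length(sim_pvalues)))
  sort(sim_pvalues, partial = k)[k]
}

new_fdr_result <- function(threshold, n_sim_below, n_exp_below, n_sim, n_exp) {
  scale <- n_exp / n_sim
  structure(list(threshold = threshold,
                 n_sim_below = n_sim_below, n_exp_below = n_exp_below,
                 n_sim = n_sim, n_exp = n_exp, scale = scale,
                 fdr = (n_sim_below * scale) / max(n_exp_below, 1L),
                 flag = if (n_exp_below == 0L) "no experimental SNP below threshold"
                        else NA_character_),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf(
    "empirical FDR: %.4g at p <= %.4g\n  %d / %d simulated, %d / %d experimental SNPs below threshold (scale %.4g)\n",
    x$fdr, x$threshold, x$n_sim_below, x$n_sim, x$n_exp_below, x$n_exp,
    x$scale))
  if (!is.na(x$flag)) cat("  note:", x$flag, "\n")
  invisible(x)
}

#' Empirical false discovery rate at a p-value threshold
#'
#' `fdr = n_sim_below * scale / max(n_exp_below, 1)` with
#' `scale = n_exp / n_sim`: the expected number of drift-only SNPs reaching
#' the threshold, rescaled to the experimental SNP count, divided by the
#' number of experimental discoveries. Ties at the threshold count as below
#' (inclusive), which can only inflate, never deflate, the FDR.
#'
#' @param exp_pvalues experimental CMH p-values.
#' @param sim_pvalues simulated (drift-only) CMH p-values.
#' @param threshold p-value cutoff, usually from [empirical_threshold()].
#' @return an `fdr_result`.
#' @export
empirical_fdr <- function(exp_pvalues, sim_pvalues, threshold) {
  check_number(threshold, "threshold", min = 0, max = 1)
  exp_pvalues <- exp_pvalues[!is.na(exp_pvalues)]
  sim_pvalues <- sim_pvalues[!is.na(sim_pvalues)]
  if (length(exp_pvalues) == 0L) stop_param("empty experimental p-value set")
  new_fdr_result(threshold,
                 n_sim_below = sum(sim_pvalues <= threshold),
                 n_exp_below = sum(exp_pvalues <= threshold),
                 n_sim = length(sim_pvalues), n_exp = length(exp_pvalues))
}

#' Empirical FDR of the top-n experimental candidates
#'
#' Sets the threshold to the n-th smallest experimental p-value (the worst
#' p-value inside the candidate set) and evaluates [empirical_fdr()] there.
#'
#' @param exp_pvalues experimental CMH p-values (needs >= `n` defined values).
#' @param sim_pvalues simulated p-values.
#' @param n candidate-set size.
#' @return an `fdr_result`.
#' @export
fdr_top_n <- function(exp_pvalues, sim_pvalues, n = 2000) {
  check_number(n, "n", min = 1, integer = TRUE)
  exp_ok <- exp_pvalues[!is.na(exp_pvalues)]
  if (length(exp_ok) < n)
    stop_param("fewer than n = ", n, " experimental p-values")
  threshold <- sort(exp_ok, partial = n)[n]
  empirical_fdr(exp_ok, sim_pvalues, threshold)
}
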