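#' Effective number of sampled chromosomes under two-stage Pool-Seq sampling
#'
#' Pool-Seq samples twice: a pool of `2 * pool_size` chromosomes from the
#' population, then `coverage` reads from the pool. The harmonic composition
#' `S = (n_pool * coverage) / (n_pool + coverage)` combines both binomial
#' sampling variances; "reads" and "pool" return the single-stage
#' alternatives.
#'
#' @param pool_size diploid individuals in the pool.
#' @param coverage read depth (vectorized).
#' @param method "two-stage", "reads", or "pool".
#' @param ploidy chromosome copies per pooled individual.
#' @return effective chromosome-sample size(s).
#' @export
effective_sample_size <- function(pool_size, coverage,
                                  method = c("two-stage", "reads", "pool"),
                                  ploidy = 2) {
  method <- match.arg(method)
  n_pool <- ploidy * pool_size
  switch(method,
         "two-stage" = (n_pool * coverage) / (n_pool + coverage),
         reads = coverage + 0 * coverage,
         pool = rep(n_pool, length(coverage)))
}

#' Standardized temporal variance of allele-frequency change
#'
#' Per SNP, `Fc = (x - y)^2 / (z (1 - z))` with `z = (x + y) / 2`; the mean
#' `F` is the ratio-of-means form `sum (x - y)^2 / sum z (1 - z)`, which is
#' more stable at extreme frequencies than the mean of per-SNP ratios. SNPs
#' not polymorphic at the first time point are dropped.
#'
#' @param x,y allele frequencies at the two time points.
#' @return list with `fc` (per-SNP, on the retained SNPs), `f_mean`,
#'   `n_used` and `used` (logical over input).
#' @export
temporal_f <- function(x, y) {
  stopifnot(length(x) == length(y))
  used <- !is.na(x) & !is.na(y) & x > 0 & x < 1
  if (!any(used)) stop_param("no SNP is polymorphic at the first time point")
  x <- x[used]; y <- y[used]
  z <- (x + y) / 2
  list(fc = (x - y)^2 / (z * (1 - z)),
       f_mean = sum((x - y)^2) / sum(z * (1 - z)),
       n_used = sum(used), used = used)
}

#' Temporal moment estimate of the effective population size
#'
#' Subtracts the two-stage sampling noise from the standardized variance of
#' allele-frequency change and inverts the drift expectation. With
#' chromosome-unit effective sample sizes `S0`, `S1` per SNP, the drift
#' component is `F_drift = F - <1/S0 + 1/S1>` (the sampling term averaged
#' with the same `z(1-z)` weights as `F`), and
#' `Ne = t / F_drift` for the haploid Wright-Fisher model used throughout
#' this package (`ploidy = "diploid"` gives the classical `t / (2 F_drift)`
#' form). A non-positive drift component means no detectable drift and
#' returns `Inf`. The confidence interval is a bootstrap percentile interval
#' over SNPs.
#'
#' @param x,y allele frequencies at the two time points.
#' @param t generations between the samples.
#' @param s0,s1 effective chromosome-sample sizes per SNP (recycled), see
#'   [effective_sample_size()].
#' @param ploidy scaling of the drift expectation.
#' @param n_boot bootstrap resamples (0 skips the interval).
#' @param conf confidence level.
#' @return object of class `ne_estimate`: list with `ne`, `f_mean`,
#'   `f_drift`, `ci`, `n_snps`, `t`, `ploidy`.
#' @export
estimate_ne <- function(x, y, t, s0, s1, ploidy = c("haploid", "diploid"),
                        n_boot = 1000, conf = 0.95) {
  ploidy <- match.arg(ploidy)
  check_number(t, "t", min = 1, integer = TRUE)
  stopifnot(length(x) == length(y))
  s0 <- rep_len(s0, length(x)); s1 <- rep_len(s1, length(x))
  point <- function(idx) {
    xi <- x[idx]; yi <- y[idx]
    use <- !is.na(xi) & !is.na(yi) & xi > 0 & xi < 1
    xi <- xi[use]; yi <- yi[use]
    if (length(xi) == 0L) return(NA_real_)
    z <- (xi + yi) / 2
    w <- z * (1 - z)
    f <- sum((xi - yi)^2) / sum(w)
    corr <- sum(w * (1 / s0[idx][use] + 1 / s1[idx][use])) / sum(w)
    fd <- f - corr
    if (fd <= 0) return(Inf)
    if (ploidy == "haploid") t / fd else t / (2 * fd)
  }
  idx_all <- seq_along(x)
  tf <- temporal_f(x, y)
  z <- (x[tf$used] + y[tf$used]) / 2
  w <- z * (1 - z)
  corr <- sum(w * (1 / s0[tf$used] + 1 / s1[tf$used])) / sum(w)
  ne <- point(idx_all)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot <- vapply(seq_len(n_boot), function(i)
      point(sample(idx_all, replace = TRUE)), 0)
    ci <- unname(quantile(boot, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                          na.rm = TRUE, names = FALSE, type = 1))
  }
  structure(list(ne = ne, f_mean = tf$f_mean, f_drift = tf$f_mean - corr,
                 ci = ci, n_snps = tf$n_used, t = t, ploidy = ploidy),
            class = "ne_estimate")
}

#' @export
print.ne_estimate <- function(x, ...) {
  cat(sprintf(
    "Ne = %s (%s, t = %d, %d SNPs, F = %.4g, drift component %.4g)\n",
    format(round(x$ne, 1)), x$ploidy, x$t, x$n_snps, x$f_mean, x$f_drift))
  if (!anyNA(x$ci))
    cat(sprintf("  bootstrap CI: [%s, %s]\n",
                format(round(x$ci[1], 1)), format(round(x$ci[2], 1))))
  invisible(x)
}

#' Subsample SNPs stratified by chromosome arm
#'
#' Draws a uniform random subset without replacement, allocating the `n`
#' draws across chromosomes proportionally to their SNP counts (largest
#' remainder rounding, so every per-arm count is within one of exact
#' proportionality).
#'
#' @param snps a `snp_table`.
#' @param n subset size.
#' @return a `snp_table` with `n` SNPs.
#' @export
subsample_snps <- function(snps, n = 1000) {
  total <- n_snps(snps)
  check_number(n, "n", min = 1, integer = TRUE)
  if (n > total) stop_param("n = ", n, " exceeds the ", total, " SNPs available")
  arms <- split(seq_len(total), snps$chrom)
  exact <- n * vapply(arms, length, 0L) / total
  alloc <- floor(exact)
  rem <- n - sum(alloc)
  if (rem > 0) {
    top_up <- order(exact - alloc, decreasing = TRUE)[seq_len(rem)]
    alloc[top_up] <- alloc[top_up] + 1L
  }
  take <- unlist(Map(function(idx, k) if (k > 0) sample(idx, k) else integer(),
                     arms, alloc), use.names = FALSE)
  snps[sort(take)]
}
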