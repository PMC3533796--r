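# Vectorized CMH core. All arguments are (sites x k) matrices:
#   a  = count in cell (1,1) (minor allele, first time point)
#   r1 = first row sum (minor allele, both time points)
#   c0, c1 = column sums (coverage at each time point)
# Strata with a zero column sum (or total < 2) are dropped per site.
cmh_core <- function(a, r1, c0, c1, correct = FALSE) {
  nt <- c0 + c1
  valid <- c0 > 0 & c1 > 0 & nt >= 2
  E <- r1 * c0 / nt
  V <- r1 * (nt - r1) * c0 * c1 / (nt^2 * (nt - 1))
  E[!valid] <- 0; V[!valid] <- 0
  a0 <- a; a0[!valid] <- 0
  S <- rowSums(a0 - E)
  SV <- rowSums(V)
  # the 0.5 correction only applies when it cannot overshoot zero
  cc <- if (correct) ifelse(abs(S) >= 0.5, 0.5, 0) else 0
  num <- abs(S) - cc
  stat <- ifelse(SV > 0, num^2 / SV, NA_real_)
  list(statistic = stat,
       p = pchisq(stat, df = 1, lower.tail = FALSE),
       k_used = rowSums(valid))
}

#' Cochran-Mantel-Haenszel statistic for one stack of 2x2 tables
#'
#' Tests, across `k` strata (replicates), whether the odds ratio relating
#' allele (rows: minor, major) to time point (columns) differs from one.
#' The statistic is `(|sum_k (a_k - E_k)| - c)^2 / sum_k V_k` with
#' `a_k` the stratum's (1,1) cell, `E_k` and `V_k` its hypergeometric mean
#' and variance, and `c = 0.5` if the continuity correction is on; it is
#' referred to a chi-squared distribution with one degree of freedom.
#' Degenerate strata (an empty row or column) are skipped; if every stratum
#' is degenerate the result is `NA`.
#'
#' @param tables a 2x2 matrix or a 2x2xk array of non-negative counts, rows =
#'   alleles, columns = time points.
#' @param continuity_correction apply the 0.5 continuity correction
#'   (off by default: Pool-Seq counts are large and the asymptotic
#'   chi-squared reference is used).
#' @return list with `statistic`, `p_value` and `k_used`.
#' @export
cmh_statistic <- function(tables, continuity_correction = FALSE) {
  if (is.matrix(tables)) tables <- array(tables, c(2, 2, 1))
  stopifnot(length(dim(tables)) == 3L, dim(tables)[1] == 2L,
            dim(tables)[2] == 2L)
  if (any(tables < 0)) stop_param("negative cell count")
  a  <- matrix(tables[1, 1, ], nrow = 1)
  r1 <- matrix(tables[1, 1, ] + tables[1, 2, ], nrow = 1)
  c0 <- matrix(tables[1, 1, ] + tables[2, 1, ], nrow = 1)
  c1 <- matrix(tables[1, 2, ] + tables[2, 2, ], nrow = 1)
  res <- cmh_core(a, r1, c0, c1, correct = continuity_correction)
  list(statistic = res$statistic, p_value = res$p, k_used = res$k_used)
}

#' SNP-wise CMH scan between two time points
#'
#' For every SNP, builds the 2x2xk stack of minor/major read counts at the
#' two time points of `contrast` (one stratum per replicate sequenced at
#' both) and computes the CMH statistic. Replicates with zero coverage at
#' either time point are dropped from that SNP's stack; `k_used` records the
#' remainder. SNPs that are monomorphic in every used population get `NA`.
#'
#' @param snps a `snp_table` whose population columns follow `design`.
#' @param design an [er_design()].
#' @param contrast length-2 character vector of time-point labels, e.g.
#'   `c("B", "M")`.
#' @param continuity_correction see [cmh_statistic()].
#' @return `data.table(chrom, pos, contrast, statistic, p, k_used)`.
#' @export
cmh_scan <- function(snps, design, contrast = c("B", "M"),
                     continuity_correction = FALSE) {
  pairs <- design_pairs(design, contrast)
  b0 <- snps$minor_counts[, pairs$idx0, drop = FALSE]
  b1 <- snps$minor_counts[, pairs$idx1, drop = FALSE]
  c0 <- snps$coverage[, pairs$idx0, drop = FALSE]
  c1 <- snps$coverage[, pairs$idx1, drop = FALSE]
  res <- cmh_core(a = b0, r1 = b0 + b1, c0 = c0, c1 = c1,
                  correct = continuity_correction)
  data.table(chrom = snps$chrom, pos = snps$pos,
             contrast = contrast_label(contrast),
             statistic = res$statistic, p = res$p, k_used = res$k_used)
}
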