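#' Draw base-population minor-allele frequencies
#'
#' The "neutral" spectrum draws an allele count `i` from a notional sample
#' of `sample_size` chromosomes with weight proportional to `1/i` (the
#' standard neutral site-frequency spectrum), folded to minor frequencies in
#' (0, 0.5]: the count `j` and `sample_size - j` contribute to the same
#' folded class. The "beta" alternative folds a Beta(shape1, shape2) draw.
#'
#' @param n_snps number of loci.
#' @param sfs "neutral" or "beta".
#' @param sample_size notional chromosome-sample size of the neutral
#'   spectrum.
#' @param shape1,shape2 Beta parameters.
#' @return vector of frequencies in (0, 0.5].
#' @export
generate_base_frequencies <- function(n_snps, sfs = "neutral",
                                      sample_size = 100, shape1 = 0.2,
                                      shape2 = 2) {
  check_number(n_snps, "n_snps", min = 1, integer = TRUE)
  if (sfs == "neutral") {
    half <- sample_size %/% 2
    j <- seq_len(half)
    w <- 1 / j + ifelse(j < sample_size - j, 1 / (sample_size - j), 0)
    sample(j / sample_size, n_snps, replace = TRUE, prob = w)
  } else if (sfs == "beta") {
    x <- rbeta(n_snps, shape1, shape2)
    x <- pmin(x, 1 - x)
    pmax(x, 1 / (2 * sample_size))  # keep strictly polymorphic
  } else stop_param("unknown sfs: ", sfs)
}

#' Define a selection model for a planted locus
#'
#' Additive (genic) selection gives the selected allele a fitness advantage
#' `s` per copy: genotype fitnesses `1 + 2s : 1 + 2hs : 1` with `h = 0.5`
#' the additive default (heterozygote advantage exactly `s`). Overdominance
#' penalizes both homozygotes, `1 - s1 : 1 : 1 - s2`, which maintains the
#' allele at the interior equilibrium `p_hat = s2 / (s1 + s2)` — the
#' mechanism used here to plant plateauing trajectories.
#'
#' @param mode "neutral", "additive" or "overdominant".
#' @param s selection coefficient per allele copy (additive mode).
#' @param h dominance of the selected allele in [0, 1] (additive mode).
#' @param s1,s2 homozygote disadvantages (overdominant mode), in (0, 1).
#' @return list of class `selection_model` (fields include `p_eq`, the
#'   overdominant equilibrium, `NA` otherwise).
#' @export
selection_model <- function(mode = c("neutral", "additive", "overdominant"),
                            s = 0, h = 0.5, s1 = 0.3, s2 = 0.45) {
  mode <- match.arg(mode)
  if (mode == "neutral") s <- 0
  if (mode == "additive") {
    check_number(s, "s", min = 0)
    check_number(h, "h", min = 0, max = 1)
    if (1 + 2 * h * s <= 0 || 1 + 2 * s <= 0) stop_param("non-positive fitness")
  }
  if (mode == "overdominant") {
    check_number(s1, "s1"); check_number(s2, "s2")
    if (s1 >= 1 || s2 >= 1 || s1 <= 0 || s2 <= 0)
      stop_param("overdominant homozygote disadvantages must be in (0, 1)")
  }
  p_eq <- if (mode == "overdominant") s2 / (s1 + s2) else NA_real_
  structure(list(mode = mode, s = s, h = h,
                 s1 = if (mode == "overdominant") s1 else NA_real_,
                 s2 = if (mode == "overdominant") s2 else NA_real_,
                 p_eq = p_eq),
            class = "selection_model")
}

#' Deterministic one-generation selection update
#'
#' Standard diploid selection recursion
#' `p' = p (w_AA p + w_Aa q) / wbar` applied before the binomial drift draw;
#' genotype fitnesses per [selection_model()]. Neutral mode is the
#' identity.
#'
#' @param p allele frequency (vectorized).
#' @param model a [selection_model()].
#' @return updated frequency.
#' @export
selection_update <- function(p, model) {
  if (any(p < 0 | p > 1)) stop_param("p must be in [0, 1]")
  w <- switch(model$mode,
    neutral = return(p),
    additive = c(AA = 1 + 2 * model$s, Aa = 1 + 2 * model$h * model$s, aa = 1),
    overdominant = c(AA = 1 - model$s1, Aa = 1, aa = 1 - model$s2))
  if (any(w <= 0)) stop_param("non-positive fitness")
  q <- 1 - p
  wbar <- w["AA"] * p^2 + 2 * w["Aa"] * p * q + w["aa"] * q^2
  unname(p * (w["AA"] * p + w["Aa"] * q) / wbar)
}

# D. melanogaster-like chromosome arms used for synthetic layouts
SYNTH_CHROMS <- c("2L" = 23e6, "2R" = 21e6, "3L" = 24e6, "3R" = 28e6,
                  "X" = 22e6)

#' Generate a complete synthetic E&R experiment
#'
#' Simulates a base population of unlinked biallelic SNPs with a realistic
#' site-frequency spectrum, propagates each replicate through binomial
#' Wright-Fisher drift at size `N` with deterministic selection applied to
#' planted loci before every drift draw, samples reads binomially at each
#' sequenced population with per-SNP coverages drawn uniformly from
#' `cov_range`, and emits a valid `sync` object together with a ground-truth
#' table and the realized allele-frequency trajectories.
#'
#' The focal (initially minor, potentially selected) allele starts at a
#' frequency drawn from the base spectrum for neutral loci and uniformly
#' from `p0_planted` for planted loci. Loci are unlinked: every trajectory
#' is independent. Call `set.seed()` first for reproducibility.
#'
#' @param n_snps number of neutral loci.
#' @param design an [er_design()].
#' @param N haploid Wright-Fisher size; defaults to `design$ne`.
#' @param planted list of `list(model = selection_model(...), n = count)`
#'   entries; planted loci are interleaved at random positions.
#' @param p0_planted range of planted starting frequencies.
#' @param sfs,sample_size base spectrum, see [generate_base_frequencies()].
#' @param cov_range per-SNP per-population coverage range (uniform integer).
#' @param chrom_sizes named vector of chromosome lengths for the layout.
#' @return list with `sync`, `truth` (`data.table`: locus, chrom, pos, mode,
#'   s, h, s1, s2, p_eq, p0), `trajectories` (`data.table`: locus,
#'   replicate, timepoint, generation, freq — the true frequencies before
#'   read sampling) and `design`.
#' @export
generate_experiment <- function(n_snps = 10000, design = default_design(),
                                N = NULL, planted = list(),
                                p0_planted = c(0.05, 0.2),
                                sfs = "neutral", sample_size = 100,
                                cov_range = c(30L, 64L),
                                chrom_sizes = SYNTH_CHROMS) {
  N <- N %||% design$ne
  check_number(N, "N", min = 2, integer = TRUE)
  n_plant <- sum(vapply(planted, function(x) x$n, 0))
  n_tot <- n_snps + n_plant
  pops <- design$populations
  P <- nrow(pops)

  # layout: loci spread over the arms proportionally to length
  arm <- sample(names(chrom_sizes), n_tot, replace = TRUE,
                prob = chrom_sizes / sum(chrom_sizes))
  pos <- vapply(chrom_sizes[arm], function(L) sample.int(L, 1L), 0L)
  ord <- order(arm, pos)
  arm <- arm[ord]; pos <- pos[ord]

  # selection mode per locus: planted loci at random indices
  models <- c(list(selection_model("neutral")),
              lapply(planted, function(x) x$model))
  mode_id <- rep(1L, n_tot)
  if (n_plant > 0) {
    slots <- sample.int(n_tot, n_plant)
    mode_id[slots] <- rep(seq_along(planted) + 1L,
                          vapply(planted, function(x) x$n, 0))
  }
  is_planted <- mode_id > 1L
  p0 <- numeric(n_tot)
  if (any(!is_planted))
    p0[!is_planted] <- generate_base_frequencies(sum(!is_planted), sfs,
                                                 sample_size)
  if (n_plant > 0)
    p0[is_planted] <- runif(n_plant, p0_planted[1], p0_planted[2])

  # two distinct alleles per locus; the focal allele is the second
  major <- sample(ACGT, n_tot, replace = TRUE)
  focal <- vapply(major, function(b) sample(setdiff(ACGT, b), 1L), "")

  # drift + selection, tracking the focal allele; record truth at each
  # sequenced generation of each replicate
  groups <- split(seq_len(n_tot), mode_id)
  p_true <- matrix(NA_real_, n_tot, P)
  for (r in unique(pops$replicate)) {
    ridx <- which(pops$replicate == r)
    ridx <- ridx[order(pops$generation[ridx])]
    p <- p0; g_now <- 0L
    for (i in ridx) {
      g <- pops$generation[i]
      while (g_now < g) {
        for (mid in names(groups)) {
          m <- models[[as.integer(mid)]]
          if (m$mode != "neutral")
            p[groups[[mid]]] <- selection_update(p[groups[[mid]]], m)
        }
        p <- rbinom(n_tot, N, p) / N
        g_now <- g_now + 1L
      }
      p_true[, i] <- p
    }
  }

  cov <- matrix(sample(seq(cov_range[1], cov_range[2]), n_tot * P, TRUE),
                n_tot, P)
  focal_reads <- matrix(rbinom(n_tot * P, as.vector(cov), as.vector(p_true)),
                        n_tot, P)
  counts <- array(0L, c(n_tot, P, 6L))
  dimnames(counts)[[3]] <- SYNC_BASES
  for (b in ACGT) {
    sel <- focal == b
    counts[sel, , b] <- counts[sel, , b] + focal_reads[sel, , drop = FALSE]
    selm <- major == b
    counts[selm, , b] <- counts[selm, , b] +
      (cov - focal_reads)[selm, , drop = FALSE]
  }
  sync <- new_sync(arm, pos, major, counts)

  truth <- data.table(
    locus = seq_len(n_tot), chrom = arm, pos = pos,
    mode = vapply(models[mode_id], function(m) m$mode, ""),
    s = vapply(models[mode_id], function(m) m$s, 0),
    h = vapply(models[mode_id], function(m) m$h, 0),
    s1 = vapply(models[mode_id], function(m) m$s1, 0),
    s2 = vapply(models[mode_id], function(m) m$s2, 0),
    p_eq = vapply(models[mode_id], function(m) m$p_eq, 0),
    focal_allele = focal, major_allele = major, p0 = p0)
  trajectories <- rbindlist(lapply(seq_len(P), function(i)
    data.table(locus = seq_len(n_tot), replicate = pops$replicate[i],
               timepoint = pops$timepoint[i], generation = pops$generation[i],
               freq = p_true[, i])))
  list(sync = sync, truth = truth, trajectories = trajectories,
       design = design)
}

#' Simulate a two-time-point temporal sample for Ne estimation
#'
#' Draws starting frequencies, applies the two-stage Pool-Seq sampling
#' (pool of `2 * pool_size` chromosomes, then `coverage` reads) at the first
#' time point, drifts the population `t` generations at haploid size `N`,
#' and samples again.
#'
#' @param n_snps number of SNPs.
#' @param N haploid population size.
#' @param t generations between samples.
#' @param pool_size diploid individuals pooled.
#' @param coverage read depth (scalar or per-SNP).
#' @param p0 starting frequencies; default Uniform(0.1, 0.9), representative
#'   intermediate-frequency SNPs as used for temporal Ne estimation.
#' @return `data.table(p0, p_t, x, y, cov0, cov1)`.
#' @export
simulate_temporal_sample <- function(n_snps = 1000, N = 200, t = 15,
                                     pool_size = 500, coverage = 50,
                                     p0 = NULL) {
  if (is.null(p0)) p0 <- runif(n_snps, 0.1, 0.9)
  n <- length(p0)
  n_pool <- 2L * pool_size
  cov0 <- rep_len(coverage, n); cov1 <- rep_len(coverage, n)
  pool0 <- rbinom(n, n_pool, p0) / n_pool
  x <- rbinom(n, cov0, pool0) / cov0
  p_t <- wf_trajectory(p0, N, t)
  pool1 <- rbinom(n, n_pool, p_t) / n_pool
  y <- rbinom(n, cov1, pool1) / cov1
  data.table(p0 = p0, p_t = p_t, x = x, y = y, cov0 = cov0, cov1 = cov1)
}
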