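# alleles considered for SNP calling, in tie-break (alphabetical) order
ACGT <- c("A", "C", "G", "T")

#' Construct a SNP table
#'
#' Container for called biallelic SNPs: per population, the minor-allele
#' count and the coverage (major + minor reads). The minor allele is defined
#' on counts summed over all populations, with alphabetical tie-breaking, so
#' its identity is stable across time points.
#'
#' @param chrom,pos site coordinates (1-based).
#' @param major,minor major/minor allele per site.
#' @param minor_counts integer matrix (sites x populations).
#' @param coverage integer matrix (sites x populations).
#' @return object of class `snp_table`.
#' @export
new_snp_table <- function(chrom, pos, major, minor, minor_counts, coverage) {
  n <- length(pos)
  minor_counts <- as.matrix(minor_counts); coverage <- as.matrix(coverage)
  stopifnot(length(chrom) == n, length(major) == n, length(minor) == n,
            nrow(minor_counts) == n, nrow(coverage) == n,
            ncol(minor_counts) == ncol(coverage))
  if (any(minor_counts > coverage))
    stop_param("minor counts exceed coverage")
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 major = as.character(major), minor = as.character(minor),
                 minor_counts = minor_counts, coverage = coverage),
            class = "snp_table")
}

#' @export
print.snp_table <- function(x, ...) {
  cat(sprintf("snp_table: %d SNPs x %d populations\n",
              length(x$pos), ncol(x$coverage)))
  invisible(x)
}

#' Number of SNPs in a snp_table
#' @param snps a `snp_table`.
#' @export
n_snps <- function(snps) length(snps$pos)

#' Subset a snp_table by site
#' @param x a `snp_table`.
#' @param i site index.
#' @param ... unused.
#' @export
`[.snp_table` <- function(x, i, ...) {
  new_snp_table(x$chrom[i], x$pos[i], x$major[i], x$minor[i],
                x$minor_counts[i, , drop = FALSE],
                x$coverage[i, , drop = FALSE])
}

#' Call biallelic SNPs from masked allele counts
#'
#' Applies the three quality filters of the scan: (i) the minor allele is
#' seen (>= 1 read) in at least `min_populations_detected` populations;
#' (ii) the minor allele is covered by at least `min_minor_total` reads
#' summed over all populations; (iii) no population's coverage exceeds
#' `max_coverage`. A site enters calling if exactly two of A/C/G/T have
#' nonzero summed counts, or if the third-ranked allele has a summed count of
#' at most `noise_max` reads, in which case it is zeroed as sequencing noise;
#' sites with a stronger third allele are dropped so that downstream tables
#' stay strictly 2 x 2 x k.
#'
#' @param sync a `sync` object (ideally after [apply_masks()]).
#' @param min_minor_total minimum summed minor-allele reads over all
#'   populations.
#' @param max_coverage maximum per-population coverage.
#' @param min_populations_detected minimum populations in which the minor
#'   allele has at least one read.
#' @param noise_max maximum summed count at which a third-ranked allele is
#'   treated as sequencing noise.
#' @return a [new_snp_table()].
#' @export
call_snps <- function(sync, min_minor_total = 10, max_coverage = 500,
                      min_populations_detected = 2, noise_max = 2) {
  check_number(min_minor_total, "min_minor_total", min = 1, integer = TRUE)
  check_number(min_populations_detected, "min_populations_detected", min = 1,
               integer = TRUE)
  if (n_sites(sync) == 0L)
    return(new_snp_table(character(), integer(), character(), character(),
                         matrix(integer(), 0, n_populations(sync)),
                         matrix(integer(), 0, n_populations(sync))))
  n <- n_sites(sync); P <- n_populations(sync)
  # per-site per-allele counts, alleles in alphabetical (tie-break) order
  acgt <- sync$counts[, , ACGT, drop = FALSE]
  totals <- apply(acgt, 3L, function(m) rowSums(matrix(m, nrow = n)))
  totals <- matrix(totals, nrow = n, dimnames = list(NULL, ACGT))
  # rank alleles: scale by 4 and add a decreasing alphabetical bonus so that
  # max.col with ties.method irrelevant picks the alphabetically first
  score <- totals * 4 + rep(3:0, each = n)
  major_i <- max.col(score, ties.method = "first")
  score2 <- score
  score2[cbind(seq_len(n), major_i)] <- -1
  minor_i <- max.col(score2, ties.method = "first")
  score3 <- score2
  score3[cbind(seq_len(n), minor_i)] <- -1
  third_i <- max.col(score3, ties.method = "first")
  major_tot <- totals[cbind(seq_len(n), major_i)]
  minor_tot <- totals[cbind(seq_len(n), minor_i)]
  third_tot <- totals[cbind(seq_len(n), third_i)]
  polymorphic <- minor_tot > 0
  biallelic <- third_tot <= noise_max   # third allele absent or zeroed as noise
  cand <- polymorphic & biallelic

  idx <- which(cand)
  take <- function(allele_i) {
    m <- matrix(0L, length(idx), P)
    for (p in seq_len(P))
      m[, p] <- acgt[cbind(idx, p, allele_i[idx])]
    m
  }
  minor_counts <- take(minor_i)
  major_counts <- take(major_i)
  coverage <- minor_counts + major_counts   # ACGT coverage after noise removal

  ok <- rowSums(minor_counts) >= min_minor_total &
    rowSums(minor_counts >= 1L) >= min_populations_detected &
    apply(coverage, 1L, max) <= max_coverage
  keep <- idx[ok]
  new_snp_table(sync$chrom[keep], sync$pos[keep],
                ACGT[major_i[keep]], ACGT[minor_i[keep]],
                minor_counts[ok, , drop = FALSE],
                coverage[ok, , drop = FALSE])
}

#' Re-apply the SNP-calling filters to an existing SNP table
#'
#' Used to subject simulated read counts to the same filtering as the
#' experimental data.
#'
#' @param snps a `snp_table`.
#' @inheritParams call_snps
#' @return list with the filtered `snp_table` (`snps`) and the logical
#'   `kept` vector.
#' @export
filter_snp_table <- function(snps, min_minor_total = 10, max_coverage = 500,
                             min_populations_detected = 2) {
  minor_tot <- rowSums(snps$minor_counts)
  det <- rowSums(snps$minor_counts >= 1L)
  maxcov <- apply(snps$coverage, 1L, max)
  kept <- minor_tot >= min_minor_total & minor_tot >= 1L &
    det >= min_populations_detected & maxcov <= max_coverage
  list(snps = snps[kept], kept = kept)
}

#' Per-population allele frequencies of called SNPs
#'
#' @param snps a `snp_table`.
#' @param allele "minor" or "major".
#' @return numeric matrix (sites x populations); populations with zero
#'   coverage are `NA`.
#' @export
site_frequencies <- function(snps, allele = c("minor", "major")) {
  allele <- match.arg(allele)
  f <- snps$minor_counts / snps$coverage
  f[snps$coverage == 0L] <- NA_real_
  if (allele == "major") f <- 1 - f
  f
}

#' Nucleotide diversity in non-overlapping windows
#'
#' Per site, the unbiased heterozygosity `n/(n-1) * (1 - sum(f_a^2))` with
#' `n` the site's A+C+G+T coverage; per window, the mean over genotyped sites
#' (coverage >= `min_coverage`). Windows with no genotyped site report
#' `pi = 0` and `n_sites = 0`. This is an approximation to the full
#' Pool-Seq estimator of diversity: read counts stand in for sampled
#' chromosomes, without the pool-size correction.
#'
#' @param sync a `sync` object.
#' @param pop population column to evaluate.
#' @param window window size in bp.
#' @param min_coverage minimum site coverage to count a site as genotyped.
#' @return `data.table` with columns chrom, window_start, window_end
#'   (1-based inclusive), pi, n_sites.
#' @export
window_pi <- function(sync, pop = 1, window = 10000, min_coverage = 2) {
  check_number(window, "window", min = 1, integer = TRUE)
  cnt <- matrix(sync$counts[, pop, ACGT], ncol = 4L)
  nn <- rowSums(cnt)
  het <- 1 - rowSums((cnt / pmax(nn, 1L))^2)
  pi_site <- ifelse(nn >= 2L, nn / (nn - 1) * het, NA_real_)
  dt <- data.table(chrom = sync$chrom, pos = sync$pos, pi_site = pi_site,
                   genotyped = nn >= min_coverage & !is.na(pi_site))
  dt[, window_start := ((pos - 1L) %/% as.integer(window)) * as.integer(window) + 1L]
  agg <- dt[, .(pi = {
    g <- genotyped
    if (any(g)) mean(pi_site[g]) else 0
  }, n_sites = sum(genotyped)), by = .(chrom, window_start)]
  # tile every chromosome from its first to its last occupied window
  out <- agg[, {
    ws <- seq(min(window_start), max(window_start), by = window)
    miss <- setdiff(ws, window_start)
    rbind(.SD, data.table(window_start = miss, pi = 0, n_sites = 0L))
  }, by = chrom]
  setorder(out, chrom, window_start)
  out[, `:=`(window_end = window_start + as.integer(window) - 1L)]
  out[, .(chrom, window_start, window_end, pi, n_sites)]
}

#' Per-chromosome change in expected heterozygosity
#'
#' Mean over SNPs and replicates of `2p(1-p)` at `t1` minus `2p(1-p)` at
#' `t0`, reported per chromosome. A negative value is a loss of
#' heterozygosity.
#'
#' @param snps a `snp_table` whose populations follow `design`.
#' @param design an [er_design()].
#' @param t0,t1 time-point labels.
#' @return `data.table(chrom, delta_h, n)`.
#' @export
heterozygosity_change <- function(snps, design, t0 = "B", t1 = "E") {
  pairs <- design_pairs(design, c(t0, t1))
  f <- site_frequencies(snps, "minor")
  h <- 2 * f * (1 - f)
  d <- h[, pairs$idx1, drop = FALSE] - h[, pairs$idx0, drop = FALSE]
  dt <- data.table(chrom = rep(snps$chrom, ncol(d)), delta = as.vector(d))
  out <- dt[!is.na(delta), .(delta_h = mean(delta), n = .N), by = chrom]
  setorder(out, chrom)
  out[]
}

#' Write / read a SNP table as tab-separated text
#'
#' Layout: chrom, pos, major, minor, then one `count:coverage` pair per
#' population.
#'
#' @param snps a `snp_table`.
#' @param path file path.
#' @export
write_snps <- function(snps, path) {
  P <- ncol(snps$coverage)
  cols <- c(list(snps$chrom, snps$pos, snps$major, snps$minor),
            lapply(seq_len(P), function(p)
              paste(snps$minor_counts[, p], snps$coverage[, p], sep = ":")))
  dt <- as.data.table(cols)
  setnames(dt, c("chrom", "pos", "major", "minor", paste0("pop", seq_len(P))))
  fwrite(dt, path, sep = "\t")
  invisible(path)
}

#' @rdname write_snps
#' @export
read_snps <- function(path) {
  dt <- fread(path, sep = "\t", header = TRUE)
  P <- ncol(dt) - 4L
  mc <- cov <- matrix(0L, nrow(dt), P)
  for (p in seq_len(P)) {
    parts <- data.table::tstrsplit(dt[[4L + p]], ":", fixed = TRUE)
    mc[, p] <- as.integer(parts[[1]])
    cov[, p] <- as.integer(parts[[2]])
  }
  new_snp_table(dt$chrom, dt$pos, dt$major, dt$minor, mc, cov)
}
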