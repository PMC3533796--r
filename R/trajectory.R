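#' The n most significant SNPs of a scan
#'
#' Orders by ascending p-value with deterministic `(chrom, pos)`
#' tie-breaking and keeps the top `n`.
#'
#' @param scan a [cmh_scan()] table.
#' @param n candidate-set size.
#' @return `data.table` of the candidates, ordered, with a `rank` column.
#' @export
top_candidates <- function(scan, n = 2000) {
  check_number(n, "n", min = 1, integer = TRUE)
  ok <- scan[!is.na(p)]
  if (nrow(ok) < n)
    stop_param("scan has only ", nrow(ok), " defined p-values, n = ", n)
  setorder(ok, p, chrom, pos)
  out <- ok[seq_len(n)]
  out[, rank := .I]
  out[]
}

#' Long-format allele-frequency trajectories
#'
#' One row per SNP, replicate and sequenced time point, holding that pool's
#' allele frequency.
#'
#' @param snps a `snp_table` following `design`.
#' @param design an [er_design()].
#' @param allele which allele's frequency to report.
#' @return `data.table(chrom, pos, replicate, timepoint, generation, freq)`.
#' @export
trajectory_table <- function(snps, design, allele = c("minor", "major")) {
  allele <- match.arg(allele)
  f <- site_frequencies(snps, allele)
  pops <- design$populations
  out <- rbindlist(lapply(seq_len(nrow(pops)), function(i)
    data.table(chrom = snps$chrom, pos = snps$pos,
               replicate = pops$replicate[i], timepoint = pops$timepoint[i],
               generation = pops$generation[i], freq = f[, i])))
  setorder(out, chrom, pos, replicate, generation)
  out[]
}

#' Orient each SNP to its selected allele
#'
#' The selected allele is the one whose mean frequency change across
#' replicates over the identification contrast is positive (the minor allele
#' rises: minor; it falls: major). An exactly zero mean change keeps the
#' minor allele and is flagged; replicates changing in opposite directions
#' are flagged "inconsistent_replicates".
#'
#' @param snps a `snp_table`.
#' @param design an [er_design()].
#' @param contrast the identification contrast, e.g. `c("B", "M")`.
#' @return `data.table(chrom, pos, selected_allele, mean_afc, flag)` where
#'   `mean_afc` is the selected allele's mean change.
#' @export
orient_selected_allele <- function(snps, design, contrast = c("B", "E")) {
  pairs <- design_pairs(design, contrast)
  f <- site_frequencies(snps, "minor")
  d <- f[, pairs$idx1, drop = FALSE] - f[, pairs$idx0, drop = FALSE]
  mean_d <- rowMeans(d, na.rm = TRUE)
  signs <- sign(d)
  mixed <- apply(signs, 1L, function(s) {
    s <- s[!is.na(s) & s != 0]
    length(unique(s)) > 1L
  })
  sel_minor <- mean_d >= 0
  flag <- rep("ok", length(mean_d))
  flag[mixed] <- "inconsistent_replicates"
  flag[mean_d == 0] <- "zero_change"
  data.table(chrom = snps$chrom, pos = snps$pos,
             selected_allele = ifelse(sel_minor, snps$minor, snps$major),
             mean_afc = ifelse(sel_minor, mean_d, -mean_d),
             flag = flag)
}

#' Trajectories of the selected allele
#'
#' Flips the minor-allele trajectories of [trajectory_table()] wherever the
#' selected allele is the major one.
#'
#' @param snps a `snp_table`.
#' @param design an [er_design()].
#' @param orientation output of [orient_selected_allele()].
#' @return long `data.table` as in [trajectory_table()].
#' @export
selected_trajectories <- function(snps, design, orientation) {
  traj <- trajectory_table(snps, design, "minor")
  key <- snp_key(orientation$chrom, orientation$pos)
  flip <- orientation$selected_allele != snps$minor[match(key,
            snp_key(snps$chrom, snps$pos))]
  flip_key <- key[flip]
  traj[snp_key(chrom, pos) %in% flip_key, freq := 1 - freq]
  traj[]
}

#' Per-replicate allele-frequency change between two time points
#'
#' @param traj long trajectory table ([trajectory_table()] or
#'   [selected_trajectories()]).
#' @param from,to time-point labels.
#' @return `data.table(chrom, pos, replicate, afc)`, one row per replicate
#'   covering both time points.
#' @export
interval_afc <- function(traj, from, to) {
  a <- traj[timepoint == from, .(chrom, pos, replicate, f0 = freq)]
  b <- traj[timepoint == to, .(chrom, pos, replicate, f1 = freq)]
  if (nrow(a) == 0L || nrow(b) == 0L)
    stop_param("time point not present in the trajectory table")
  m <- merge(a, b, by = c("chrom", "pos", "replicate"))
  m[, .(chrom, pos, replicate, afc = f1 - f0)]
}

#' Summarize per-replicate AFC per SNP
#'
#' @param afc output of [interval_afc()].
#' @param fun "mean" (default summary across replicates) or "median".
#' @return `data.table(chrom, pos, afc)`.
#' @export
afc_summary <- function(afc, fun = c("mean", "median")) {
  fun <- match.arg(fun)
  f <- if (fun == "mean") function(x) mean(x, na.rm = TRUE)
       else function(x) median(x, na.rm = TRUE)
  afc[, .(afc = f(afc)), by = .(chrom, pos)]
}

#' Classify candidate trajectories as plateau, continuous or other
#'
#' With `rise = AFC(B->M)` and `late = AFC(M->E)` of the selected allele
#' (replicate-mean by default):
#' `plateau` if `rise >= rise_min` and `|late| <= flat_max`;
#' `continuous` if `rise >= rise_min / 2` and `late >= flat_max`;
#' otherwise `other`. `plateau` takes precedence on the boundary, so the
#' labels partition the candidate set.
#'
#' When a threshold is `NULL` it is set automatically: `rise_min` to the
#' median candidate rise, and `flat_max` to the 95th percentile of the
#' absolute late-interval change of drift-simulated (null) SNPs — the drift
#' envelope that a genuinely flat trajectory must stay inside.
#'
#' @param rise,late numeric vectors, per-candidate AFC summaries.
#' @param rise_min,flat_max classification thresholds, or `NULL` for auto.
#' @param null_late late-interval AFC of null-simulated SNPs, required when
#'   `flat_max` is `NULL`.
#' @return factor of labels with attributes `rise_min` and `flat_max`.
#' @export
classify_trajectories <- function(rise, late, rise_min = NULL, flat_max = NULL,
                                  null_late = NULL) {
  stopifnot(length(rise) == length(late))
  if (is.null(rise_min)) rise_min <- median(rise, na.rm = TRUE)
  if (is.null(flat_max)) {
    if (is.null(null_late))
      stop_param("`flat_max = NULL` needs `null_late` (the drift envelope)")
    flat_max <- unname(quantile(abs(null_late), 0.95, na.rm = TRUE))
  }
  if (rise_min <= 0 || flat_max <= 0)
    stop_param("classification thresholds must be positive")
  lab <- ifelse(rise >= rise_min & abs(late) <= flat_max, "plateau",
         ifelse(rise >= rise_min / 2 & late >= flat_max, "continuous",
                "other"))
  lab <- factor(lab, levels = c("plateau", "continuous", "other"))
  attr(lab, "rise_min") <- rise_min
  attr(lab, "flat_max") <- flat_max
  lab
}

#' Fraction of candidates whose selected allele reached a frequency
#'
#' @param freqs selected-allele frequencies at the queried time point
#'   (replicate-mean or per-replicate values).
#' @param threshold frequency cutoff in (0, 1].
#' @param inclusive count `freq >= threshold` (`TRUE`, fixation-style
#'   `>= 0.99`) or `freq > threshold` (`FALSE`, `> 0.90`-style).
#' @return the fraction of non-missing entries meeting the cutoff.
#' @export
fixation_fraction <- function(freqs, threshold = 0.99, inclusive = TRUE) {
  check_number(threshold, "threshold")
  if (threshold <= 0 || threshold > 1)
    stop_param("`threshold` must be in (0, 1]")
  freqs <- freqs[!is.na(freqs)]
  if (inclusive) mean(freqs >= threshold) else mean(freqs > threshold)
}

#' Overlap between two candidate sets
#'
#' @param a,b data.frames with `chrom` and `pos` columns.
#' @return list with `count` (shared SNPs) and `fraction` (`count / nrow(a)`).
#' @export
candidate_overlap <- function(a, b) {
  ka <- unique(snp_key(a$chrom, a$pos))
  kb <- unique(snp_key(b$chrom, b$pos))
  count <- length(intersect(ka, kb))
  list(count = count, fraction = count / length(ka))
}

#' Median AFC in distance bins flanking the candidate SNPs
#'
#' Stacks windows around every candidate: each non-candidate SNP within
#' `span` bp contributes its AFC to the bin `ceiling(distance / bin_width)`
#' (both sides pooled), once per candidate it flanks. Candidate SNPs are
#' excluded from all bins, so any elevation must come from linked flanking
#' SNPs. A parallel curve for position-adjusted control loci, shifted
#' `control_offset` bp upstream, estimates the local background.
#'
#' @param candidates data.frame with `chrom`, `pos`.
#' @param snp_afc `data.table(chrom, pos, afc)` for all SNPs (e.g. the
#'   replicate-mean base-to-final change).
#' @param bin_width bin width in bp.
#' @param span maximum distance in bp.
#' @param control_offset upstream shift of the control loci in bp.
#' @return `data.table(set, bin, dist_lo, dist_hi, median_afc, n_snps)`.
#' @export
flanking_decay <- function(candidates, snp_afc, bin_width = 100, span = 1000,
                           control_offset = 500000) {
  if (span < bin_width) stop_param("`span` must be >= `bin_width`")
  snp_afc <- as.data.table(snp_afc)
  cand_key <- unique(snp_key(candidates$chrom, candidates$pos))
  universe <- snp_afc[!snp_key(chrom, pos) %in% cand_key]
  bin_one <- function(centers, label) {
    ctr <- data.table(chrom = centers$chrom, center = centers$pos,
                      lo = centers$pos - as.integer(span),
                      hi = centers$pos + as.integer(span))
    u <- universe[, .(chrom, pos, afc, lo = pos, hi = pos)]
    data.table::setkey(ctr, chrom, lo, hi)
    ov <- data.table::foverlaps(u, ctr, type = "within", nomatch = NULL)
    ov[, dist := abs(pos - center)]
    ov <- ov[dist > 0]
    ov[, bin := ceiling(dist / bin_width)]
    ov[, .(median_afc = median(afc, na.rm = TRUE), n_snps = .N,
           set = label), by = bin]
  }
  cand <- data.table(chrom = candidates$chrom, pos = candidates$pos)
  ctrl <- data.table(chrom = candidates$chrom,
                     pos = pmax(candidates$pos - as.integer(control_offset), 1L))
  out <- rbind(bin_one(cand, "candidate"), bin_one(ctrl, "control"))
  out[, `:=`(dist_lo = (bin - 1L) * as.integer(bin_width) + 1L,
             dist_hi = bin * as.integer(bin_width))]
  setorder(out, set, bin)
  out[, .(set, bin, dist_lo, dist_hi, median_afc, n_snps)]
}
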