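#' Define a gene model
#'
#' One transcript of a gene: its span, exon structure, coding region and
#' UTRs in genomic coordinates (1-based closed), plus optionally the coding
#' sequence (spliced, 5'->3' in transcript orientation) for
#' synonymous/non-synonymous calls.
#'
#' @param gene_id gene identifier.
#' @param chrom chromosome.
#' @param strand "+" or "-".
#' @param tx_start,tx_end transcript span.
#' @param exons,cds,utr5,utr3 two-column matrices of (start, end) rows, or
#'   `NULL`.
#' @param cds_seq coding sequence as a character string (length = summed CDS
#'   width, divisible by 3), or `NULL`.
#' @param transcript_id transcript identifier (defaults to the gene id).
#' @return list of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, tx_start, tx_end,
                       exons = NULL, cds = NULL, utr5 = NULL, utr3 = NULL,
                       cds_seq = NULL, transcript_id = gene_id) {
  if (!strand %in% c("+", "-")) stop_param("strand must be '+' or '-'")
  as_mat <- function(m) {
    if (is.null(m)) return(NULL)
    m <- matrix(as.integer(m), ncol = 2)
    m[order(m[, 1]), , drop = FALSE]
  }
  cds <- as_mat(cds)
  if (!is.null(cds_seq)) {
    if (is.null(cds)) stop_param("cds_seq given without cds intervals")
    w <- sum(cds[, 2] - cds[, 1] + 1L)
    if (nchar(cds_seq) != w)
      stop_param("cds_seq length ", nchar(cds_seq),
                 " does not match CDS width ", w)
    if (w %% 3L != 0L) stop_param("CDS width must be divisible by 3")
  }
  structure(list(gene_id = gene_id, transcript_id = transcript_id,
                 chrom = chrom, strand = strand,
                 tx_start = as.integer(tx_start), tx_end = as.integer(tx_end),
                 exons = as_mat(exons), cds = cds,
                 utr5 = as_mat(utr5), utr3 = as_mat(utr3),
                 cds_seq = if (is.null(cds_seq)) NULL else toupper(cds_seq)),
            class = "gene_model")
}

#' Bundle gene models
#'
#' @param models list of [gene_model()] objects.
#' @return list of class `gene_model_set`.
#' @export
gene_model_set <- function(models) {
  if (inherits(models, "gene_model")) models <- list(models)
  stopifnot(all(vapply(models, inherits, TRUE, "gene_model")))
  structure(list(models = models), class = "gene_model_set")
}

in_intervals <- function(pos, m) {
  if (is.null(m) || nrow(m) == 0L) return(FALSE)
  any(pos >= m[, 1] & pos <= m[, 2])
}

# map a genomic position inside the CDS to its 1-based position along the
# spliced coding sequence (transcript orientation)
cds_offset <- function(pos, model) {
  cds <- model$cds
  widths <- cds[, 2] - cds[, 1] + 1L
  hit <- which(pos >= cds[, 1] & pos <= cds[, 2])
  if (length(hit) == 0L) return(NA_integer_)
  if (model$strand == "+") {
    before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
    before + (pos - cds[hit, 1]) + 1L
  } else {
    nseg <- nrow(cds)
    after <- if (hit < nseg) sum(widths[seq(hit + 1L, nseg)]) else 0L
    after + (cds[hit, 2] - pos) + 1L
  }
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# classify a biallelic substitution inside the CDS
coding_effect <- function(pos, a1, a2, model) {
  if (is.null(model$cds_seq)) return(NA_character_)
  off <- cds_offset(pos, model)
  if (is.na(off)) return(NA_character_)
  if (model$strand == "-") {
    a1 <- COMPLEMENT[[a1]]; a2 <- COMPLEMENT[[a2]]
  }
  codon_i <- (off - 1L) %/% 3L
  within <- (off - 1L) %% 3L + 1L
  codon <- substr(model$cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
  sub_in <- function(codon, b) {
    substr(codon, within, within) <- b
    codon
  }
  aa <- function(codon) {
    gc <- Biostrings::GENETIC_CODE
    if (grepl("N", codon)) NA_character_ else unname(gc[codon])
  }
  aa1 <- aa(sub_in(codon, a1)); aa2 <- aa(sub_in(codon, a2))
  if (is.na(aa1) || is.na(aa2)) return(NA_character_)
  if (aa1 == aa2) "synonymous" else "nonsynonymous"
}

# features of one SNP with respect to one transcript; character(0) if the
# SNP is unrelated to the transcript
transcript_features <- function(pos, a1, a2, model, flank) {
  if (pos >= model$tx_start && pos <= model$tx_end) {
    if (in_intervals(pos, model$cds)) {
      eff <- coding_effect(pos, a1, a2, model)
      if (is.na(eff))
        stop_param(sprintf(
          "annotation error: coding SNP at %s:%d in %s but no usable coding sequence",
          model$chrom, pos, model$transcript_id))
      return(eff)
    }
    if (in_intervals(pos, model$utr5)) return("utr5")
    if (in_intervals(pos, model$utr3)) return("utr3")
    if (is.null(model$exons) || in_intervals(pos, model$exons))
      return(character(0))  # exonic but non-coding, non-UTR: no feature class
    return("intron")
  }
  # outside the transcript: up/downstream within `flank` of the gene ends,
  # strand-aware (5' end upstream, 3' end downstream)
  left <- pos < model$tx_start && pos >= model$tx_start - flank
  right <- pos > model$tx_end && pos <= model$tx_end + flank
  if (left) return(if (model$strand == "+") "upstream" else "downstream")
  if (right) return(if (model$strand == "+") "downstream" else "upstream")
  character(0)
}

#' Map SNPs to genomic features
#'
#' Evaluates every SNP against every overlapping transcript: coding
#' positions are classified synonymous/non-synonymous from the coding
#' sequence, non-coding exonic positions in the UTRs as `utr5`/`utr3`,
#' other intragenic positions as `intron`, and positions within `flank` bp
#' of the transcript ends as `upstream`/`downstream` (strand-aware). A SNP
#' matching no transcript is `intergenic` (exclusive of all other labels);
#' a SNP can carry several features from alternative transcripts or
#' overlapping genes, each counted separately. SNPs in a coding region whose
#' transcript lacks a usable coding sequence are skipped with a warning.
#'
#' @param snps a `snp_table`, or a data.frame with `chrom`, `pos` and
#'   optionally `major`, `minor` (needed for coding calls).
#' @param models a [gene_model_set()].
#' @param flank upstream/downstream window in bp.
#' @return `data.table(chrom, pos, feature, gene_id)`; `gene_id` is `NA` for
#'   intergenic SNPs.
#' @export
annotate_snps <- function(snps, models, flank = 200) {
  if (inherits(snps, "snp_table"))
    snps <- data.table(chrom = snps$chrom, pos = snps$pos,
                       major = snps$major, minor = snps$minor)
  snps <- as.data.table(snps)
  if (!"major" %in% names(snps)) snps[, `:=`(major = "N", minor = "N")]
  out <- vector("list", nrow(snps))
  n_err <- 0L
  for (i in seq_len(nrow(snps))) {
    feats <- list()
    for (m in models$models) {
      if (m$chrom != snps$chrom[i]) next
      fs <- tryCatch(
        transcript_features(snps$pos[i], snps$major[i], snps$minor[i], m,
                            flank),
        error = function(e) { n_err <<- n_err + 1L; character(0) })
      if (length(fs))
        feats[[length(feats) + 1L]] <- data.table(feature = fs,
                                                  gene_id = m$gene_id)
    }
    out[[i]] <- if (length(feats)) {
      u <- unique(rbindlist(feats))
      data.table(chrom = snps$chrom[i], pos = snps$pos[i],
                 feature = u$feature, gene_id = u$gene_id)
    } else {
      data.table(chrom = snps$chrom[i], pos = snps$pos[i],
                 feature = "intergenic", gene_id = NA_character_)
    }
  }
  if (n_err > 0L)
    warning(n_err, " coding SNP(s) skipped: no usable coding sequence")
  rbindlist(out)
}

pearson_2x2 <- function(a, b, c, d) {
  # chi-square without continuity correction, 1 df
  n <- a + b + c + d
  e <- outer(c(a + b, c + d), c(a + c, b + d)) / n
  o <- matrix(c(a, c, b, d), 2)
  stat <- sum((o - e)^2 / e)
  list(stat = stat, p = pchisq(stat, 1, lower.tail = FALSE),
       odds_ratio = (a * d) / (b * c))
}

#' Feature over/under-representation of candidate SNPs
#'
#' Per feature, cross-tabulates candidate against non-candidate SNPs by
#' carrying versus not carrying the feature, and reports the Pearson
#' chi-square (1 df), odds ratio and direction. A SNP carrying several
#' features contributes to each feature's table; each feature is tested
#' against its own complement.
#'
#' @param candidates data.frame with `chrom`, `pos` (a subset of the
#'   annotated SNPs).
#' @param annotations output of [annotate_snps()] for all SNPs.
#' @return `data.table(feature, cand_in, cand_out, non_in, non_out, chisq,
#'   p, odds_ratio, direction)`.
#' @export
feature_enrichment <- function(candidates, annotations) {
  annotations <- as.data.table(annotations)
  cand_key <- unique(snp_key(candidates$chrom, candidates$pos))
  all_key <- unique(snp_key(annotations$chrom, annotations$pos))
  n_cand <- sum(all_key %in% cand_key)
  n_non <- length(all_key) - n_cand
  feats <- setdiff(unique(annotations$feature), NA)
  out <- lapply(feats, function(f) {
    key_f <- unique(annotations[feature == f, snp_key(chrom, pos)])
    a <- sum(key_f %in% cand_key)          # candidates with the feature
    c_ <- length(key_f) - a                # non-candidates with the feature
    b <- n_cand - a; d <- n_non - c_
    if (length(key_f) == 0L || (b == 0L && d == 0L)) return(NULL)
    ch <- pearson_2x2(a, b, c_, d)
    data.table(feature = f, cand_in = a, cand_out = b, non_in = c_,
               non_out = d, chisq = ch$stat, p = ch$p,
               odds_ratio = ch$odds_ratio,
               direction = if (a / max(n_cand, 1) >= c_ / max(n_non, 1))
                 "over" else "under")
  })
  rbindlist(out)
}

#' Regional over/under-representation of candidate SNPs
#'
#' Cross-tabulates candidates and non-candidates by membership in a genomic
#' region (for example a chromosome arm, the X chromosome, or the span of an
#' inversion) and reports the Pearson chi-square and odds ratio, alongside
#' the fraction of all SNPs versus the fraction of candidates inside the
#' region.
#'
#' @param candidates data.frame with `chrom`, `pos`.
#' @param all_snps data.frame with `chrom`, `pos` for the SNP universe.
#' @param region a `GRanges` describing the region.
#' @return one-row `data.table`; degenerate tables (region holds all or no
#'   SNPs) are flagged with `NA` statistics.
#' @export
region_enrichment <- function(candidates, all_snps, region) {
  if (length(region) == 0L) stop_param("empty region")
  all_dt <- unique(data.table(chrom = all_snps$chrom, pos = all_snps$pos))
  gr <- GenomicRanges::GRanges(all_dt$chrom,
                               IRanges::IRanges(all_dt$pos, all_dt$pos))
  all_dt[, in_region := GenomicRanges::countOverlaps(gr, region) > 0]
  all_dt[, is_cand := snp_key(chrom, pos) %in%
           snp_key(candidates$chrom, candidates$pos)]
  a <- all_dt[is_cand & in_region, .N]; b <- all_dt[is_cand & !in_region, .N]
  c_ <- all_dt[!is_cand & in_region, .N]; d <- all_dt[!is_cand & !in_region, .N]
  degenerate <- (a + c_ == 0L) || (b + d == 0L)
  ch <- if (degenerate) list(stat = NA_real_, p = NA_real_,
                             odds_ratio = NA_real_)
        else pearson_2x2(a, b, c_, d)
  data.table(cand_in = a, cand_out = b, non_in = c_, non_out = d,
             frac_candidates_in = a / max(a + b, 1L),
             frac_all_in = (a + c_) / max(a + b + c_ + d, 1L),
             chisq = ch$stat, p = ch$p, odds_ratio = ch$odds_ratio,
             flag = if (degenerate) "degenerate" else NA_character_)
}
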