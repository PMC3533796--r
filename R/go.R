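#' Read a gene-to-GO association file
#'
#' Tab-separated: first field the gene id, the remaining field(s) GO term
#' identifiers separated by tabs, spaces, commas or semicolons.
#'
#' @param path file path.
#' @return `data.table(gene_id, go_id)`, one row per association.
#' @export
read_go_map <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    gos <- unlist(strsplit(paste(f[-1], collapse = " "), "[,; ]+"))
    gos <- gos[nzchar(gos)]
    if (length(gos)) data.table(gene_id = f[1], go_id = gos) else NULL
  })
  unique(rbindlist(out))
}

# gene sets induced by SNPs under the "gene span +/- flank" definition
snp_gene_map <- function(snps, models, flank = 200) {
  snps <- as.data.table(snps)[, .(chrom, pos)]
  genes <- unique(rbindlist(lapply(models$models, function(m)
    data.table(gene_id = m$gene_id, chrom = m$chrom,
               start = m$tx_start, end = m$tx_end))))
  genes <- genes[, .(start = min(start), end = max(end)),
                 by = .(gene_id, chrom)]
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom,
    IRanges::IRanges(pmax(genes$start - flank, 1L), genes$end + flank))
  gr_snps <- GenomicRanges::GRanges(snps$chrom,
                                    IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(gr_snps, gr_genes)
  map <- vector("list", nrow(snps))
  sp <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
              S4Vectors::queryHits(hits))
  map[as.integer(names(sp))] <- sp
  map[vapply(map, is.null, TRUE)] <- list(character(0))
  map
}

#' SNP-permutation test of GO category enrichment
#'
#' Long genes contain more SNPs and therefore collect more false-positive
#' candidates; a gene-level Fisher test is then biased toward categories of
#' long genes. This permutation procedure removes the bias by resampling at
#' the SNP level: each permutation draws SNPs uniformly without replacement
#' from the SNP universe until the induced gene set (genes whose span, plus
#' `flank` bp on each side, contains a drawn SNP) is as large as the
#' observed candidate gene set, and records how many genes of each GO
#' category were hit. The empirical p-value of a category is
#' `(1 + #permutations with hits >= observed) / (1 + n_perm)`, bounded below
#' by `1 / (1 + n_perm)`.
#'
#' Two multiple-testing summaries are reported: Benjamini-Hochberg over the
#' empirical p-values, and (optionally) the permutation-ensemble empirical
#' FDR — at each observed p-value, the expected number of categories
#' reaching it in a permutation divided by the number observed to reach it.
#'
#' @param candidates data.frame with `chrom`, `pos` of the candidate SNPs.
#' @param all_snps data.frame with `chrom`, `pos` of the SNP universe
#'   (must contain the candidates).
#' @param models a [gene_model_set()].
#' @param go_map `data.table(gene_id, go_id)` associations.
#' @param n_perm number of permutations.
#' @param flank gene-definition flank in bp.
#' @param empirical_fdr also compute the permutation-ensemble FDR (keeps an
#'   `n_perm` x categories count matrix in memory).
#' @return `data.table(go_id, n_genes, observed, expected, p_empirical,
#'   fdr_bh[, fdr_empirical])`, one row per GO term with at least one
#'   annotatable gene; terms without annotatable genes are dropped and
#'   listed in attribute `"excluded"`.
#' @export
go_permutation_test <- function(candidates, all_snps, models, go_map,
                                n_perm = 100000, flank = 200,
                                empirical_fdr = TRUE) {
  check_number(n_perm, "n_perm", min = 1, integer = TRUE)
  go_map <- unique(as.data.table(go_map))
  map <- snp_gene_map(all_snps, models, flank)
  gene_universe <- sort(unique(unlist(map)))
  excluded <- setdiff(unique(go_map$go_id),
                      unique(go_map[gene_id %in% gene_universe, go_id]))
  go_map <- go_map[gene_id %in% gene_universe]
  terms <- sort(unique(go_map$go_id))
  G <- length(terms)
  if (G == 0L) stop_param("no GO term has an annotatable gene")
  # gene x term membership
  mem <- matrix(FALSE, length(gene_universe), G,
                dimnames = list(gene_universe, terms))
  mem[cbind(match(go_map$gene_id, gene_universe),
            match(go_map$go_id, terms))] <- TRUE

  key_all <- snp_key(as.data.table(all_snps)$chrom, as.data.table(all_snps)$pos)
  key_cand <- unique(snp_key(candidates$chrom, candidates$pos))
  cand_idx <- which(key_all %in% key_cand)
  cand_genes <- unique(unlist(map[cand_idx]))
  target <- length(cand_genes)
  if (target == 0L) stop_param("no candidate SNP maps to a gene")
  observed <- colSums(mem[cand_genes, , drop = FALSE])

  # flattened SNP->gene map for fast permutation walks
  lens <- lengths(map)
  flat_genes <- match(unlist(map), gene_universe)
  starts <- cumsum(c(0L, lens))
  n_snp <- length(map)

  counts <- if (empirical_fdr) matrix(0L, n_perm, G) else NULL
  ge_obs <- integer(G)
  for (i in seq_len(n_perm)) {
    ord <- sample.int(n_snp)
    gl <- lens[ord]
    # gene indices in draw order
    gidx <- flat_genes[sequence(gl, from = starts[ord] + 1L)]
    new <- !duplicated(gidx)
    # cumulative number of distinct genes after each drawn SNP
    cum <- cumsum(new)
    per_snp <- cum[cumsum(gl)]
    stop_at <- which(per_snp >= target)[1]
    if (is.na(stop_at)) stop_at <- n_snp
    upto <- sum(gl[seq_len(stop_at)])
    drawn <- unique(gidx[seq_len(upto)])
    cnt <- colSums(mem[drawn, , drop = FALSE])
    ge_obs <- ge_obs + (cnt >= observed)
    if (empirical_fdr) counts[i, ] <- cnt
  }
  p_emp <- (1 + ge_obs) / (1 + n_perm)
  out <- data.table(go_id = terms, n_genes = colSums(mem),
                    observed = as.integer(observed),
                    expected = if (empirical_fdr) colMeans(counts)
                               else NA_real_,
                    p_empirical = p_emp,
                    fdr_bh = p.adjust(p_emp, "BH"))
  if (empirical_fdr) {
    # per-term count threshold that attains each observed p-value, then the
    # expected number of "significant" terms per permutation at that level
    fdr_e <- vapply(seq_len(G), function(g) {
      thr <- vapply(seq_len(G), function(j) {
        # smallest count c for term j with empirical p <= p_emp[g]
        cs <- counts[, j]
        cand_c <- sort(unique(c(cs, observed[j])))
        pj <- vapply(cand_c, function(cc) (1 + sum(cs >= cc)) / (1 + n_perm), 0)
        ok <- which(pj <= p_emp[g])
        if (length(ok)) cand_c[ok[1]] else Inf
      }, 0)
      exp_sig <- mean(rowSums(sweep(counts, 2, thr, ">=")))
      obs_sig <- sum(p_emp <= p_emp[g])
      min(1, exp_sig / max(obs_sig, 1L))
    }, 0)
    out[, fdr_empirical := fdr_e]
  }
  setorder(out, p_empirical, go_id)
  attr(out, "excluded") <- excluded
  attr(out, "n_candidate_genes") <- target
  out[]
}

#' Naive gene-level Fisher test of GO enrichment
#'
#' The biased baseline that [go_permutation_test()] corrects: genes are the
#' sampling unit, candidate genes are tested against the gene universe per
#' GO term with Fisher's exact test, ignoring that long genes are more
#' likely to be hit by chance.
#'
#' @inheritParams go_permutation_test
#' @return `data.table(go_id, n_genes, observed, p_fisher)`.
#' @export
go_fisher_test <- function(candidates, all_snps, models, go_map, flank = 200) {
  go_map <- unique(as.data.table(go_map))
  map <- snp_gene_map(all_snps, models, flank)
  gene_universe <- sort(unique(unlist(map)))
  go_map <- go_map[gene_id %in% gene_universe]
  key_all <- snp_key(as.data.table(all_snps)$chrom, as.data.table(all_snps)$pos)
  key_cand <- unique(snp_key(candidates$chrom, candidates$pos))
  cand_genes <- unique(unlist(map[key_all %in% key_cand]))
  out <- go_map[, {
    in_go <- unique(gene_id)
    a <- length(intersect(cand_genes, in_go))
    b <- length(cand_genes) - a
    c_ <- length(in_go) - a
    d <- length(gene_universe) - length(cand_genes) - c_
    p <- stats::fisher.test(matrix(c(a, b, c_, d), 2),
                            alternative = "greater")$p.value
    .(n_genes = length(in_go), observed = a, p_fisher = p)
  }, by = go_id]
  setorder(out, p_fisher)
  out[]
}
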