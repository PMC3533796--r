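# a two-gene annotation playground:
#   gA (+ strand): tx 101-300, exon1 101-160, exon2 201-300, CDS 121-129
#     spliced CDS "ATGGATTAA" (Met-Asp-stop), 5'UTR 101-120, 3'UTR 130-160
#   gB (- strand): tx 250-600, single exon 250-600 annotated UTR-free
demo_models <- function() {
  gene_model_set(list(
    gene_model("gA", "2L", "+", 101, 300,
               exons = rbind(c(101, 160), c(201, 300)),
               cds = rbind(c(121, 129)),
               utr5 = rbind(c(101, 120)), utr3 = rbind(c(130, 160)),
               cds_seq = "ATGGATTAA"),
    gene_model("gB", "2L", "-", 250, 600,
               exons = rbind(c(250, 600)))))
}

test_that("coding SNPs are classified by the genetic code", {
  models <- demo_models()
  # codon 2 is GAT (Asp) at 124-126; third position T->C gives GAC (Asp)
  syn <- annotate_snps(data.frame(chrom = "2L", pos = 126L,
                                  major = "T", minor = "C"), models)
  expect_true("synonymous" %in% syn$feature)
  # second position A->G gives GGT (Gly): nonsynonymous
  nsyn <- annotate_snps(data.frame(chrom = "2L", pos = 125L,
                                   major = "A", minor = "G"), models)
  expect_true("nonsynonymous" %in% nsyn$feature)
})

test_that("UTR, intron, flank and intergenic rules apply", {
  models <- demo_models()
  ann <- function(pos) annotate_snps(data.frame(chrom = "2L", pos = pos,
                                                major = "A", minor = "T"),
                                     models)
  expect_true("utr5" %in% ann(110L)$feature)
  expect_true("utr3" %in% ann(150L)$feature)
  expect_true("intron" %in% ann(180L)$feature)      # between gA's exons
  # 150 bp past gA's 3' end -> downstream of gA
  a450 <- ann(450L)
  expect_true("downstream" %in% a450$feature)
  # 250 bp past gA's end the gA label disappears
  a551 <- ann(551L)
  expect_false("downstream" %in% a551$feature)
  # 150 bp before gA start -> upstream on the + strand
  expect_true("upstream" %in% ann(31L)$feature)
  # gB is on the - strand: 150 bp beyond its right end is upstream
  expect_true("upstream" %in% ann(750L)$feature)
  # 250 bp past every gene -> intergenic
  far <- ann(851L)
  expect_equal(far$feature, "intergenic")
  expect_true(is.na(far$gene_id))
})

test_that("overlapping genes contribute separate features per gene", {
  models <- demo_models()
  # position 180: intron of gA and within 200 bp of gB's left (3') end
  mixed <- annotate_snps(data.frame(chrom = "2L", pos = 180L,
                                    major = "A", minor = "T"), models)
  expect_setequal(mixed$feature, c("intron", "downstream"))
  expect_equal(mixed$gene_id[mixed$feature == "intron"], "gA")
  expect_equal(mixed$gene_id[mixed$feature == "downstream"], "gB")
  # annotation is independent of gene-model input order
  rev_models <- gene_model_set(rev(models$models))
  mixed_rev <- annotate_snps(data.frame(chrom = "2L", pos = 180L,
                                        major = "A", minor = "T"), rev_models)
  expect_setequal(paste(mixed$feature, mixed$gene_id),
                  paste(mixed_rev$feature, mixed_rev$gene_id))
})

test_that("feature enrichment matches the Pearson chi-square", {
  # hand-constructed table [[30, 70], [100, 900]]
  ch <- erscan:::pearson_2x2(30, 70, 100, 900)
  ref <- chisq.test(matrix(c(30, 100, 70, 900), 2), correct = FALSE)
  expect_equal(ch$stat, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(ch$p, unname(ref$p.value), tolerance = 1e-12)

  # proportional candidates: odds ratio 1, p = 1
  ann <- data.table::data.table(
    chrom = "2L", pos = 1:1000,
    feature = rep(c("intron", "intergenic"), c(100, 900)),
    gene_id = NA_character_)
  cand <- data.frame(chrom = "2L", pos = c(1:10, 101:190))
  fe <- feature_enrichment(cand, ann)
  expect_equal(fe$odds_ratio, c(1, 1), tolerance = 1e-12)
  expect_equal(fe$p, c(1, 1), tolerance = 1e-12)
})

test_that("region enrichment contrasts region against complement", {
  all_snps <- data.frame(chrom = rep(c("X", "3R"), c(200, 800)),
                         pos = c(1:200, 1:800))
  cand <- data.frame(chrom = rep(c("X", "3R"), c(2, 98)),
                     pos = c(1:2, 1:98))
  reg <- GenomicRanges::GRanges("X", IRanges::IRanges(1, 1e6))
  r <- region_enrichment(cand, all_snps, reg)
  expect_equal(r$cand_in, 2L)
  expect_equal(r$frac_all_in, 0.2)
  expect_equal(r$frac_candidates_in, 0.02)
  expect_lt(r$p, 0.001)          # strong under-representation on X
  expect_lt(r$odds_ratio, 1)

  whole <- GenomicRanges::GRanges(c("X", "3R"),
                                  IRanges::IRanges(c(1, 1), c(1e6, 1e6)))
  expect_equal(region_enrichment(cand, all_snps, whole)$flag, "degenerate")
  expect_error(region_enrichment(cand, all_snps, GenomicRanges::GRanges()),
               "empty")
})

test_that("GO permutation p-values match exhaustive enumeration on the toy universe", {
  u <- toy_go_universe()
  cand <- u$all_snps[c(1, 4), ]   # genes g1, g2
  go_genes <- list("GO:A" = "g1", "GO:B" = c("g2", "g3"), "GO:C" = "g4",
                   "GO:D" = c("g1", "g4"))
  observed <- list("GO:A" = 1, "GO:B" = 1, "GO:C" = 0, "GO:D" = 1)
  exact <- toy_go_exact_p(u$snp_gene, go_genes, observed)
  set.seed(61)
  res <- go_permutation_test(cand, u$all_snps, u$models, u$go_map,
                             n_perm = 20000, empirical_fdr = FALSE)
  for (g in names(go_genes)) {
    p_pkg <- res$p_empirical[res$go_id == g]
    expect_lt(abs(p_pkg - exact[[g]]), 0.02)
  }
  # guaranteed lower bound
  expect_true(all(res$p_empirical >= 1 / (1 + 20000)))
  # a category observed at 0 hits has p = 1 under >= comparison
  expect_equal(res$p_empirical[res$go_id == "GO:C"], 1)
})

test_that("SNP permutation removes the gene-length bias a Fisher test has", {
  set.seed(67)
  n_long <- 20; n_short <- 20
  models <- list(); snps <- list(); gid <- 0
  mkgene <- function(id, chrom, start, n_snp, width) {
    list(model = gene_model(id, chrom, "+", start, start + width),
         snps = data.frame(chrom = chrom,
                           pos = as.integer(seq(start + 10, start + width - 10,
                                                length.out = n_snp))))
  }
  pos0 <- 1000
  for (i in 1:n_long) {
    g <- mkgene(paste0("L", i), "2L", pos0, 20, 20000); pos0 <- pos0 + 30000
    models <- c(models, list(g$model)); snps <- c(snps, list(g$snps))
  }
  for (i in 1:n_short) {
    g <- mkgene(paste0("S", i), "2L", pos0, 2, 2000); pos0 <- pos0 + 10000
    models <- c(models, list(g$model)); snps <- c(snps, list(g$snps))
  }
  models <- gene_model_set(models)
  all_snps <- do.call(rbind, snps)
  go_map <- data.table::data.table(
    gene_id = c(paste0("L", 1:n_long), paste0("S", 1:n_short)),
    go_id = rep(c("GO:long", "GO:short"), c(n_long, n_short)))
  # candidates: a uniformly random SNP subset (no signal at all)
  cand <- all_snps[sample.int(nrow(all_snps), 60), ]
  perm <- go_permutation_test(cand, all_snps, models, go_map,
                              n_perm = 2000, empirical_fdr = FALSE)
  fish <- go_fisher_test(cand, all_snps, models, go_map)
  p_perm_long <- perm$p_empirical[perm$go_id == "GO:long"]
  p_fish_long <- fish$p_fisher[fish$go_id == "GO:long"]
  expect_lt(p_fish_long, 0.01)   # naive test: spurious enrichment
  expect_gt(p_perm_long, 0.05)   # permutation test: none
})
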