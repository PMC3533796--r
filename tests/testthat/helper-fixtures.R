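# shared fixture builders ---------------------------------------------------

# write sync lines to a temp file and return the path
write_sync_text <- function(lines) {
  f <- tempfile(fileext = ".sync")
  writeLines(lines, f)
  f
}

# a minimal design: k replicates, each sequenced at B (gen 0) and E (gen t),
# optionally M in between
two_point_design <- function(k = 3, t = 15, ne = 200) {
  er_design(data.frame(
    pop = c(paste0("B", 1:k), paste0("E", 1:k)),
    replicate = rep(1:k, 2),
    timepoint = rep(c("B", "E"), each = k),
    generation = rep(c(0L, as.integer(t)), each = k)), ne = ne)
}

three_point_design <- function(k = 3, ne = 200) {
  er_design(data.frame(
    pop = c(paste0("B", 1:k), paste0("M", 1:k), paste0("E", 1:k)),
    replicate = rep(1:k, 3),
    timepoint = rep(c("B", "M", "E"), each = k),
    generation = rep(c(0L, 15L, 37L), each = k)), ne = ne)
}

# snp_table from a minor-frequency matrix at fixed coverage
snp_table_from_freqs <- function(freqs, coverage = 100, chrom = "2L",
                                 pos = seq_len(nrow(freqs))) {
  cov <- matrix(as.integer(coverage), nrow(freqs), ncol(freqs))
  new_snp_table(rep(chrom, nrow(freqs)), pos,
                rep("A", nrow(freqs)), rep("T", nrow(freqs)),
                matrix(as.integer(round(freqs * cov)), nrow(freqs)),
                cov)
}

# the 20-line hand-written sync fixture used for filter determinism;
# hand-derived surviving positions: 1, 5, 8, 9, 11, 12, 13
hand_sync_lines <- function() {
  pop0 <- "30:0:0:0:0:0"
  c(
    # 1: minor T, total 12 in 4 pops -> called
    paste(c("2L", 1, "A", rep("27:3:0:0:0:0", 4), rep(pop0, 2)), collapse = "\t"),
    # 2: minor total 9 -> rejected
    paste(c("2L", 2, "A", rep("27:3:0:0:0:0", 3), rep(pop0, 3)), collapse = "\t"),
    # 3: minor 10 reads but one population -> rejected
    paste(c("2L", 3, "A", "20:10:0:0:0:0", rep(pop0, 5)), collapse = "\t"),
    # 4: coverage 501 in population 1 -> rejected
    paste(c("2L", 4, "A", "489:12:0:0:0:0", rep("27:3:0:0:0:0", 3),
            rep(pop0, 2)), collapse = "\t"),
    # 5: third allele C with 2 reads total -> zeroed as noise, called
    paste(c("2L", 5, "A", "26:4:1:0:0:0", "26:4:1:0:0:0", "26:4:0:0:0:0",
            rep(pop0, 3)), collapse = "\t"),
    # 6: third allele with 3 reads -> site dropped
    paste(c("2L", 6, "A", "25:4:2:0:0:0", "26:4:1:0:0:0", "26:4:0:0:0:0",
            rep(pop0, 3)), collapse = "\t"),
    # 7: monomorphic -> dropped
    paste(c("2L", 7, "A", rep(pop0, 6)), collapse = "\t"),
    # 8: C major / G minor, total 10 in 2 pops -> called
    paste(c("2L", 8, "C", "0:0:25:5:0:0", "0:0:25:5:0:0",
            rep("0:0:30:0:0:0", 4)), collapse = "\t"),
    # 9: minor total 10, detected in 2 -> called
    paste(c("2L", 9, "A", "25:5:0:0:0:0", "25:5:0:0:0:0", rep(pop0, 4)),
          collapse = "\t"),
    # 10: minor total 9, detected in 2 -> rejected
    paste(c("2L", 10, "A", "25:5:0:0:0:0", "26:4:0:0:0:0", rep(pop0, 4)),
          collapse = "\t"),
    # 11: A/T tie, alphabetical tie-break (A major) -> called
    paste(c("2L", 11, "A", rep("15:15:0:0:0:0", 6)), collapse = "\t"),
    # 12: N and del reads ignored in coverage -> called
    paste(c("2L", 12, "A", "27:3:0:0:5:2", rep("27:3:0:0:0:0", 3),
            rep(pop0, 2)), collapse = "\t"),
    # 13: coverage exactly 500 is allowed -> called
    paste(c("2L", 13, "A", "488:12:0:0:0:0", rep("27:3:0:0:0:0", 3),
            rep(pop0, 2)), collapse = "\t"),
    # 14-20: monomorphic or single-read filler -> dropped
    vapply(14:19, function(i)
      paste(c("2L", i, "G", rep("0:0:0:30:0:0", 6)), collapse = "\t"), ""),
    paste(c("2L", 20, "A", "29:1:0:0:0:0", rep(pop0, 5)), collapse = "\t")
  )
}

hand_sync_survivors <- c(1L, 5L, 8L, 9L, 11L, 12L, 13L)

# independent loop-based evaluation of the CMH closed form (test oracle)
cmh_brute <- function(tables, correct = FALSE) {
  k <- dim(tables)[3]
  S <- 0; V <- 0; used <- 0
  for (i in seq_len(k)) {
    tb <- tables[, , i]
    a <- tb[1, 1]; b <- tb[1, 2]; c_ <- tb[2, 1]; d <- tb[2, 2]
    n <- a + b + c_ + d
    if ((a + c_) == 0 || (b + d) == 0 || n < 2) next
    S <- S + (a - (a + b) * (a + c_) / n)
    V <- V + (a + b) * (c_ + d) * (a + c_) * (b + d) / (n^2 * (n - 1))
    used <- used + 1
  }
  if (V == 0) return(list(statistic = NA_real_, p = NA_real_))
  num <- abs(S) - if (correct && abs(S) >= 0.5) 0.5 else 0
  stat <- num^2 / V
  list(statistic = stat, p = pchisq(stat, 1, lower.tail = FALSE))
}

random_stack <- function(k = 3, max_count = 50) {
  array(sample.int(max_count, 4 * k, replace = TRUE), c(2, 2, k))
}

# toy GO universe: 4 single-gene SNP sets, exact enumeration feasible
toy_go_universe <- function() {
  models <- gene_model_set(list(
    gene_model("g1", "2L", "+", 1000, 5000),
    gene_model("g2", "2L", "+", 10000, 11000),
    gene_model("g3", "2L", "+", 20000, 21000),
    gene_model("g4", "2L", "+", 30000, 31000)))
  all_snps <- data.frame(chrom = "2L",
                         pos = c(1500L, 2500L, 3500L, 10500L, 20500L, 30500L))
  snp_gene <- c("g1", "g1", "g1", "g2", "g3", "g4")
  go_map <- data.table::data.table(
    gene_id = c("g1", "g2", "g3", "g4", "g1", "g4"),
    go_id = c("GO:A", "GO:B", "GO:B", "GO:C", "GO:D", "GO:D"))
  list(models = models, all_snps = all_snps, snp_gene = snp_gene,
       go_map = go_map)
}

# exact probability that each GO term reaches its observed hit count when
# SNPs are drawn without replacement until 2 distinct genes are hit,
# by enumeration over all orderings of the 6 single-gene SNPs
toy_go_exact_p <- function(snp_gene, go_genes, observed) {
  n <- length(snp_gene)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  hits <- sapply(names(go_genes), function(g) 0)
  all_orders <- perms(seq_len(n))
  for (ord in all_orders) {
    genes <- character()
    for (s in ord) {
      genes <- union(genes, snp_gene[s])
      if (length(genes) >= 2) break
    }
    for (g in names(go_genes))
      if (sum(go_genes[[g]] %in% genes) >= observed[[g]])
        hits[g] <- hits[g] + 1
  }
  hits / length(all_orders)
}
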