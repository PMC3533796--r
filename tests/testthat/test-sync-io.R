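test_that("read_sync maps fields and rejects malformed lines", {
  f <- write_sync_text(c("2L\t100\tA\t10:0:0:5:0:0\t12:0:0:3:0:0"))
  s <- read_sync(f, 2)
  expect_equal(s$chrom, "2L")
  expect_equal(s$pos, 100L)
  expect_equal(s$ref, "A")
  expect_equal(s$counts[1, 1, ], c(A = 10L, T = 0L, C = 0L, G = 5L,
                                   N = 0L, del = 0L))
  expect_equal(s$counts[1, 2, ], c(A = 12L, T = 0L, C = 0L, G = 3L,
                                   N = 0L, del = 0L))

  empty <- write_sync_text(character())
  expect_equal(n_sites(read_sync(empty, 2)), 0L)

  expect_error(read_sync(f, 3), "line 1")
  bad <- write_sync_text(c("2L\t100\tA\t10:0:0:5:0:0\t12:0:0:3:0:0",
                           "2L\t101\tA\t10:0:0:-5:0:0\t12:0:0:3:0:0"))
  expect_error(read_sync(bad, 2), "non-negative integer")
})

test_that("sync files round-trip byte-for-byte", {
  lines <- c("2L\t100\tA\t10:0:0:5:0:0\t12:0:0:3:0:0",
             "2L\t200\tC\t0:1:20:0:0:0\t0:0:22:2:1:1",
             "X\t7\tT\t0:30:0:0:0:0\t3:27:0:0:0:0")
  f <- write_sync_text(lines)
  g <- tempfile()
  write_sync(read_sync(f, 2), g)
  expect_identical(readLines(g), lines)
})

test_that("pileup parsing follows the samtools grammar", {
  expect_equal(unname(pileup_to_counts("A", "..,,")),
               c(4L, 0L, 0L, 0L, 0L, 0L))
  # '$' and the +2 insertion are consumed without counting
  expect_equal(unname(pileup_to_counts("A", ".$.,+2TTg")),
               c(3L, 0L, 0L, 1L, 0L, 0L))
  # one of two bases below the quality threshold
  expect_equal(unname(pileup_to_counts("C", "..", "I#", 20)),
               c(0L, 0L, 1L, 0L, 0L, 0L))
  # deletions counted in the del slot; ^X consumed
  expect_equal(unname(pileup_to_counts("A", "^I.*,")),
               c(2L, 0L, 0L, 0L, 0L, 1L))
  expect_error(pileup_to_counts("A", "..", "I"), "quality characters")
  # total never exceeds the number of base columns
  set.seed(1)
  for (i in 1:20) {
    nb <- sample(1:10, 1)
    bases <- paste(sample(c(".", ",", "a", "T", "*"), nb, TRUE), collapse = "")
    expect_lte(sum(pileup_to_counts("G", bases)), nb)
  }
})

test_that("indel masks take min_reads, flanks, and merging into account", {
  m <- build_indel_mask(data.frame(chrom = "2L", pos = 100L,
                                   population = "p1", supporting_reads = 2L))
  expect_equal(IRanges::start(m$indels), 95L)
  expect_equal(IRanges::end(m$indels), 105L)

  m0 <- build_indel_mask(data.frame(chrom = rep("2L", 3), pos = rep(50L, 3),
                                    population = c("p1", "p2", "p3"),
                                    supporting_reads = c(1L, 1L, 1L)))
  expect_equal(length(m0$indels), 0L)

  m2 <- build_indel_mask(data.frame(chrom = c("2L", "2L"), pos = c(100L, 108L),
                                    population = "p1",
                                    supporting_reads = c(2L, 3L)))
  expect_equal(length(m2$indels), 1L)
  expect_equal(IRanges::start(m2$indels), 95L)
  expect_equal(IRanges::end(m2$indels), 113L)

  expect_error(build_indel_mask(data.frame(chrom = "2L", pos = 1L,
                                           population = "p1",
                                           supporting_reads = 5L),
                                flank = -1), "flank")
})

test_that("BED masks convert from 0-based half-open to 1-based closed", {
  skip_if_not_installed("rtracklayer")
  bed <- tempfile(fileext = ".bed")
  writeLines("2L\t89\t110", bed)   # BED: 0-based half-open [89, 110)
  m <- read_mask(bed, "excluded")
  expect_equal(IRanges::start(m$excluded), 90L)
  expect_equal(IRanges::end(m$excluded), 110L)
})

test_that("apply_masks drops exactly the covered sites and is idempotent", {
  counts <- array(5L, c(10, 2, 6))
  s <- new_sync(rep("2L", 10), 1:10 * 10L, rep("A", 10), counts)
  masks <- mask_set(excluded = GenomicRanges::GRanges(
    "2L", IRanges::IRanges(c(90, 15), c(110, 35))))
  out <- suppressMessages(apply_masks(s, masks))
  # brute-force membership: positions 20, 30, 90, 100, 110 masked
  expect_equal(out$pos, c(10L, 40L, 50L, 60L, 70L, 80L))
  expect_equal(unname(attr(out, "dropped")["excluded"]), 4L)
  twice <- suppressMessages(apply_masks(out, masks))
  expect_equal(twice$pos, out$pos)

  # masks on chromosomes absent from the data are ignored with a warning
  other <- mask_set(excluded = GenomicRanges::GRanges(
    "3R", IRanges::IRanges(1, 1e6)))
  expect_warning(kept <- suppressMessages(apply_masks(s, other)), "absent")
  expect_equal(kept$pos, s$pos)
})
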