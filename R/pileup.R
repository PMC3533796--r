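#' Convert one pileup base column to allele counts
#'
#' Parses the samtools text-pileup base string of a single population and
#' returns A/T/C/G/N/del counts. The supported grammar is the subset needed
#' for count extraction: `.`/`,` (reference base on either strand), explicit
#' bases `ACGTN`/`acgtn`, `*` (deletion), read starts `^` followed by one
#' mapping-quality character, read ends `$`, and indel specifications
#' `+N<seq>` / `-N<seq>` which are consumed without counting (indels are
#' handled by masking, not by genotyping). Bases whose quality is below
#' `min_base_quality` are dropped.
#'
#' @param ref reference base of the site.
#' @param bases pileup base string.
#' @param quals base-quality string (one character per counted column); `NULL`
#'   accepts every base.
#' @param min_base_quality minimum phred base quality.
#' @param qual_offset ASCII offset of the quality encoding (33 for Sanger).
#' @return named integer vector of counts, ordered A, T, C, G, N, del.
#' @export
pileup_to_counts <- function(ref, bases, quals = NULL, min_base_quality = 20,
                             qual_offset = 33) {
  ref <- toupper(ref)
  counts <- stats::setNames(integer(6), SYNC_BASES)
  ch <- strsplit(bases, "", fixed = TRUE)[[1]]
  qv <- if (is.null(quals)) NULL else
    as.integer(charToRaw(quals)) - qual_offset
  i <- 1L; qi <- 0L
  n <- length(ch)
  while (i <= n) {
    c0 <- ch[i]
    if (c0 == "^") {           # read start: skip the mapping-quality char
      i <- i + 2L
    } else if (c0 == "$") {    # read end marker
      i <- i + 1L
    } else if (c0 == "+" || c0 == "-") {   # indel: +N<seq> / -N<seq>
      j <- i + 1L
      while (j <= n && grepl("[0-9]", ch[j])) j <- j + 1L
      len <- as.integer(paste(ch[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
    } else {
      # a counted column: consumes one quality character
      qi <- qi + 1L
      ok <- is.null(qv) || (qi <= length(qv) && qv[qi] >= min_base_quality)
      base <- switch(toupper(c0),
                     "." = ref, "," = ref, "*" = "del",
                     "A" = "A", "C" = "C", "G" = "G", "T" = "T", "N" = "N",
                     stop_param("pileup format error: unexpected character '",
                                c0, "'"))
      if (ok) counts[base] <- counts[base] + 1L
      i <- i + 1L
    }
  }
  if (!is.null(qv) && qi != length(qv))
    stop_param(sprintf(
      "pileup format error: %d base columns but %d quality characters",
      qi, length(qv)))
  counts
}

#' Read a simplified samtools pileup file into a sync object
#'
#' Expects the per-population text pileup layout
#' `chrom pos ref depth bases quals` with one `(depth, bases, quals)` triple
#' per population.
#'
#' @param path file path.
#' @param n_populations number of populations in the file.
#' @inheritParams pileup_to_counts
#' @return a [new_sync()] object.
#' @export
read_pileup <- function(path, n_populations = 1, min_base_quality = 20) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  counts <- array(0L, c(n, n_populations, 6L))
  chrom <- character(n); pos <- integer(n); ref <- character(n)
  for (k in seq_len(n)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3L + 3L * n_populations)
      stop_param(sprintf("pileup format error at line %d: %d fields, expected %d",
                         k, length(f), 3L + 3L * n_populations))
    chrom[k] <- f[1]; pos[k] <- as.integer(f[2]); ref[k] <- f[3]
    for (p in seq_len(n_populations)) {
      o <- 3L + (p - 1L) * 3L
      counts[k, p, ] <- pileup_to_counts(f[3], f[o + 2L], f[o + 3L],
                                         min_base_quality = min_base_quality)
    }
  }
  new_sync(chrom, pos, ref, counts)
}
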