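SYNC_BASES <- c("A", "T", "C", "G", "N", "del")

#' Construct a sync object
#'
#' A `sync` holds per-site, per-population allele counts in the PoPoolation2
#' sync convention: one A:T:C:G:N:del count sextuple per population.
#'
#' @param chrom character vector of chromosome names.
#' @param pos 1-based integer positions.
#' @param ref reference base per site (A, C, G, T or N).
#' @param counts integer array of dimension (sites, populations, 6), third
#'   dimension ordered A, T, C, G, N, del.
#' @return object of class `sync`.
#' @export
new_sync <- function(chrom, pos, ref, counts) {
  n <- length(pos)
  if (length(chrom) != n || length(ref) != n)
    stop_param("chrom, pos and ref must have equal length")
  if (length(dim(counts)) != 3L || dim(counts)[1] != n || dim(counts)[3] != 6L)
    stop_param("`counts` must be an (sites x populations x 6) array")
  if (any(counts < 0)) stop_param("counts must be non-negative")
  if (any(pos < 1)) stop_param("positions are 1-based and must be >= 1")
  dimnames(counts)[[3]] <- SYNC_BASES
  structure(list(chrom = as.character(chrom), pos = as.integer(pos),
                 ref = as.character(ref), counts = counts),
            class = "sync")
}

#' @export
print.sync <- function(x, ...) {
  cat(sprintf("sync: %d sites x %d populations on %d chromosome(s)\n",
              length(x$pos), dim(x$counts)[2], length(unique(x$chrom))))
  invisible(x)
}

#' Number of sites / populations in a sync object
#' @param sync a `sync` object.
#' @export
n_sites <- function(sync) length(sync$pos)

#' @rdname n_sites
#' @export
n_populations <- function(sync) dim(sync$counts)[2]

#' Read a sync file
#'
#' Reads the tab-separated sync format: `chrom pos ref A:T:C:G:N:del ...`,
#' one count column per population. Malformed lines (wrong column count,
#' non-integer or negative counts) raise an error naming the first offending
#' line.
#'
#' @param path file path.
#' @param n_populations expected number of population columns.
#' @return a [new_sync()] object.
#' @export
read_sync <- function(path, n_populations) {
  check_number(n_populations, "n_populations", min = 1, integer = TRUE)
  if (!file.exists(path)) stop_param("no such file: ", path)
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) {
    counts <- array(integer(), c(0L, n_populations, 6L))
    return(new_sync(character(), integer(), character(), counts))
  }
  bad <- which(nf != 3L + n_populations)
  if (length(bad))
    stop_param(sprintf(
      "sync format error at line %d: %d fields, expected %d (3 + %d populations)",
      bad[1], nf[bad[1]], 3L + n_populations, n_populations))
  dt <- fread(path, sep = "\t", header = FALSE, colClasses = "character",
              quote = "")
  n <- nrow(dt)
  pos <- suppressWarnings(as.integer(dt[[2]]))
  if (anyNA(pos))
    stop_param("sync format error at line ", which(is.na(pos))[1],
               ": position is not an integer")
  counts <- array(NA_integer_, c(n, n_populations, 6L))
  for (p in seq_len(n_populations)) {
    parts <- data.table::tstrsplit(dt[[3L + p]], ":", fixed = TRUE)
    if (length(parts) != 6L)
      stop_param("sync format error: population column ", p,
                 " does not hold A:T:C:G:N:del sextuples")
    for (b in 1:6) {
      v <- suppressWarnings(as.integer(parts[[b]]))
      bad <- which(is.na(v) | v < 0 | parts[[b]] != as.character(v))
      if (length(bad))
        stop_param(sprintf(
          "sync format error at line %d: count '%s' is not a non-negative integer",
          bad[1], parts[[b]][bad[1]]))
      counts[, p, b] <- v
    }
  }
  new_sync(dt[[1]], pos, dt[[3]], counts)
}

#' Write a sync file
#'
#' Inverse of [read_sync()]; well-formed files round-trip byte-for-byte.
#'
#' @param sync a `sync` object.
#' @param path output path.
#' @export
write_sync <- function(sync, path) {
  n <- n_sites(sync)
  P <- n_populations(sync)
  cols <- vector("list", 3L + P)
  cols[[1]] <- sync$chrom
  cols[[2]] <- sync$pos
  cols[[3]] <- sync$ref
  for (p in seq_len(P))
    cols[[3L + p]] <- do.call(paste, c(lapply(1:6, function(b) sync$counts[, p, b]),
                                       sep = ":"))
  fwrite(as.data.table(cols), path, sep = "\t", col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Positional masks
#'
#' A `mask_set` stores merged genomic intervals to exclude from analysis,
#' under the labels `repeats` (simple repeats / transposable elements),
#' `indels` (indel neighborhoods) and `excluded` (manually excluded regions
#' such as a spreading low-frequency haplotype or an amplified gene cluster).
#'
#' @param repeats,indels,excluded `GRanges` of positions to drop (1-based,
#'   closed intervals, the Bioconductor convention).
#' @return object of class `mask_set`: a named list of reduced `GRanges`.
#' @export
mask_set <- function(repeats = NULL, indels = NULL, excluded = NULL) {
  grs <- list(repeats = repeats, indels = indels, excluded = excluded)
  grs <- grs[!vapply(grs, is.null, TRUE)]
  grs <- lapply(grs, function(g) {
    if (!methods::is(g, "GRanges")) stop_param("masks must be GRanges")
    GenomicRanges::reduce(g)
  })
  structure(grs, class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  for (lab in names(x))
    cat(sprintf("%s: %d interval(s), %s bp\n", lab, length(x[[lab]]),
                format(sum(IRanges::width(x[[lab]])), big.mark = ",")))
  invisible(x)
}

#' Read a mask from a BED or GFF file
#'
#' BED input is 0-based half-open and GFF 1-based closed; `rtracklayer`
#' performs the conversion to the internal 1-based closed `GRanges`.
#'
#' @param path file path.
#' @param label one of "repeats", "indels", "excluded".
#' @return a [mask_set()] with one populated label.
#' @export
read_mask <- function(path, label = c("excluded", "repeats", "indels")) {
  label <- match.arg(label)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop_param("reading BED/GFF masks requires the rtracklayer package")
  gr <- rtracklayer::import(path)
  args <- stats::setNames(list(gr), label)
  do.call(mask_set, args)
}

#' Build an indel mask from indel calls
#'
#' Every indel supported by at least `min_reads` reads in at least one
#' population is masked together with `flank` nucleotides on both sides
#' (closed range `pos - flank` .. `pos + flank`); overlapping ranges are
#' merged.
#'
#' @param indel_calls data.frame with columns `chrom`, `pos` (1-based),
#'   `population`, `supporting_reads`.
#' @param flank flanking nucleotides masked on each side.
#' @param min_reads minimum supporting reads in any one population.
#' @return a [mask_set()] with the `indels` label populated.
#' @export
build_indel_mask <- function(indel_calls, flank = 5, min_reads = 2) {
  check_number(flank, "flank", min = 0, integer = TRUE)
  check_number(min_reads, "min_reads", min = 1, integer = TRUE)
  keep <- indel_calls$supporting_reads >= min_reads
  ic <- indel_calls[keep, , drop = FALSE]
  if (nrow(ic) == 0L)
    return(mask_set(indels = GenomicRanges::GRanges()))
  gr <- GenomicRanges::GRanges(
    ic$chrom,
    IRanges::IRanges(pmax(1L, ic$pos - flank), ic$pos + flank))
  mask_set(indels = gr)
}

#' Combine mask sets
#'
#' @param ... `mask_set` objects.
#' @return a single `mask_set` with per-label unions.
#' @export
combine_masks <- function(...) {
  sets <- list(...)
  labs <- unique(unlist(lapply(sets, names)))
  out <- lapply(labs, function(lab) {
    grs <- lapply(sets, function(s) s[[lab]])
    grs <- grs[!vapply(grs, is.null, TRUE)]
    GenomicRanges::reduce(do.call(c, grs))
  })
  structure(stats::setNames(out, labs), class = "mask_set")
}

#' Drop masked sites from a sync object
#'
#' Sites whose position falls in any mask interval are removed; input order
#' is preserved. The number of sites dropped per label is reported via
#' `message()` and attached as attribute `"dropped"`.
#'
#' @param sync a `sync` object.
#' @param masks a [mask_set()].
#' @return the filtered `sync`.
#' @export
apply_masks <- function(sync, masks) {
  if (n_sites(sync) == 0L) return(sync)
  site_gr <- GenomicRanges::GRanges(sync$chrom,
                                    IRanges::IRanges(sync$pos, sync$pos))
  hit_any <- rep(FALSE, n_sites(sync))
  dropped <- integer(0)
  for (lab in names(masks)) {
    unknown <- setdiff(as.character(GenomicRanges::seqnames(masks[[lab]])),
                       unique(sync$chrom))
    if (length(unknown))
      warning("mask '", lab, "' names chromosomes absent from the data: ",
              paste(unknown, collapse = ", "), call. = FALSE)
    # suppress the seqlevel-merge notice for those same absent chromosomes
    hits <- suppressWarnings(
      GenomicRanges::countOverlaps(site_gr, masks[[lab]])) > 0
    dropped[lab] <- sum(hits & !hit_any)
    hit_any <- hit_any | hits
  }
  keep <- !hit_any
  out <- new_sync(sync$chrom[keep], sync$pos[keep], sync$ref[keep],
                  sync$counts[keep, , , drop = FALSE])
  message(sprintf("apply_masks: dropped %d of %d sites (%s)",
                  sum(!keep), length(keep),
                  paste(sprintf("%s: %d", names(dropped), dropped),
                        collapse = ", ")))
  attr(out, "dropped") <- dropped
  out
}
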