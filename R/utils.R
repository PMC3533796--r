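#' @importFrom data.table data.table as.data.table setDT setorder := .N .SD fread fwrite setnames rbindlist
#' @importFrom stats rbinom pchisq quantile median runif rbeta rpois p.adjust ks.test
#' @importFrom utils head count.fields
NULL

# silence R CMD check notes for data.table NSE columns
utils::globalVariables(c(
  ".", "afc", "bin", "center", "chrom", "contrast", "delta", "dist", "f0",
  "f1", "fdr_empirical", "feature", "freq", "gene_id", "generation",
  "genotyped", "go_id", "in_region", "is_cand", "k_used", "label", "locus",
  "mean_afc", "median_afc", "p", "pi_site", "pos", "rank", "replicate",
  "selected_allele", "set", "statistic", "timepoint", "window_start"
))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_param(sprintf("`%s` must be a single number", name))
  if (x < min || x > max)
    stop_param(sprintf("`%s` must be in [%s, %s]", name, min, max))
  if (integer && x != round(x))
    stop_param(sprintf("`%s` must be an integer", name))
  invisible(x)
}

# key used to match SNPs across tables
snp_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

# md5 digest of an arbitrary R object (used for config provenance)
object_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}
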