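#' Run the full selection-scan pipeline from one configuration
#'
#' Orchestrates mask -> call -> CMH scan -> drift null -> empirical FDR ->
#' candidates -> trajectories -> classification, writing one tab-separated
#' output per stage plus a JSON manifest with content digests. A stage is
#' recomputed only when its output is missing, older than any of its inputs,
#' or `force = TRUE`; deleting one intermediate therefore recomputes that
#' stage and its dependents on the next run.
#'
#' Configuration (list, or path to a YAML file):
#' \describe{
#'   \item{seed}{integer seed for all randomness.}
#'   \item{design}{an [er_design()], a design-YAML path, or absent for
#'     [default_design()].}
#'   \item{input}{either `list(sync = path, n_populations = k)` or
#'     `list(synthetic = list(n_snps = ..., additive = list(n, s),
#'     overdominant = list(n, s1, s2)))`.}
#'   \item{masks}{optional `list(excluded = bed, repeats = gff,
#'     indels = tsv, flank = 5, min_indel_reads = 2)`.}
#'   \item{snp_calling}{`list(min_minor_total, max_coverage,
#'     min_populations_detected)`.}
#'   \item{contrasts}{list of length-2 time-point vectors; default B-M, B-E
#'     and M-E.}
#'   \item{null}{`list(n_snps)`, size of the drift-null simulation (default:
#'     the experimental SNP count).}
#'   \item{fdr}{`list(top_fraction = 1e-5, top_n = 2000)`.}
#'   \item{candidates}{`list(n = 2000)`.}
#' }
#'
#' @param config configuration list or YAML path.
#' @param out_dir output directory (created if needed).
#' @param force recompute every stage.
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir, force = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  design <- config$design %||% default_design()
  if (is.character(design)) design <- read_design(design)
  v <- validate_design(design)
  if (!v$ok) stop_param("invalid design: ", paste(v$errors, collapse = "; "))
  contrasts <- lapply(config$contrasts %||%
                        list(c("B", "M"), c("B", "E"), c("M", "E")),
                      as.character)
  cp <- config$snp_calling %||% list()
  fdr_cfg <- config$fdr %||% list()
  n_cand <- (config$candidates %||% list())$n %||% 2000

  digest <- object_digest(config)
  path <- function(f) file.path(out_dir, f)
  log_file <- path("pipeline.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    paste0(...))
    cat(line, "\n", file = log_file, append = TRUE)
    message(line)
  }
  stale <- function(outs, ins = character()) {
    if (force) return(TRUE)
    if (!all(file.exists(outs))) return(TRUE)
    ins <- ins[file.exists(ins)]
    length(ins) > 0 &&
      min(file.mtime(outs)) < max(file.mtime(ins))
  }

  # --- stage: input -------------------------------------------------------
  f_sync <- path("input.sync")
  truth_file <- path("truth.tsv")
  if (!is.null(config$input$sync)) {
    in_sync <- config$input$sync
    n_pop <- config$input$n_populations %||% nrow(design$populations)
  } else {
    syn <- config$input$synthetic %||% list()
    if (stale(f_sync)) {
      logmsg("input: generating synthetic experiment")
      set.seed(seed)
      planted <- list()
      if (!is.null(syn$additive))
        planted <- c(planted, list(list(
          model = selection_model("additive", s = syn$additive$s %||% 0.1),
          n = syn$additive$n %||% 100)))
      if (!is.null(syn$overdominant))
        planted <- c(planted, list(list(
          model = selection_model("overdominant",
                                  s1 = syn$overdominant$s1 %||% 0.3,
                                  s2 = syn$overdominant$s2 %||% 0.45),
          n = syn$overdominant$n %||% 50)))
      gen <- generate_experiment(n_snps = syn$n_snps %||% 10000,
                                 design = design, planted = planted)
      write_sync(gen$sync, f_sync)
      fwrite(gen$truth, truth_file, sep = "\t")
    }
    in_sync <- f_sync
    n_pop <- nrow(design$populations)
  }

  # --- stage: mask --------------------------------------------------------
  f_masked <- path("masked.sync")
  if (!is.null(config$masks)) {
    if (stale(f_masked, in_sync)) {
      logmsg("mask: applying positional masks")
      mk <- config$masks
      sets <- list()
      if (!is.null(mk$excluded)) sets <- c(sets, list(read_mask(mk$excluded, "excluded")))
      if (!is.null(mk$repeats)) sets <- c(sets, list(read_mask(mk$repeats, "repeats")))
      if (!is.null(mk$indels)) {
        ind <- fread(mk$indels)
        sets <- c(sets, list(build_indel_mask(ind, flank = mk$flank %||% 5,
                                              min_reads = mk$min_indel_reads %||% 2)))
      }
      sync <- read_sync(in_sync, n_pop)
      sync <- apply_masks(sync, do.call(combine_masks, sets))
      write_sync(sync, f_masked)
    }
  } else f_masked <- in_sync

  # --- stage: call --------------------------------------------------------
  f_snps <- path("snps.tsv")
  if (stale(f_snps, f_masked)) {
    logmsg("call: SNP calling")
    sync <- read_sync(f_masked, n_pop)
    snps <- call_snps(sync,
                      min_minor_total = cp$min_minor_total %||% 10,
                      max_coverage = cp$max_coverage %||% 500,
                      min_populations_detected = cp$min_populations_detected %||% 2)
    write_snps(snps, f_snps)
    logmsg("call: ", n_snps(snps), " SNPs")
  }
  snps <- read_snps(f_snps)

  # --- stage: scan --------------------------------------------------------
  f_scan <- vapply(contrasts, function(ct)
    path(sprintf("cmh_%s.tsv", contrast_label(ct))), "")
  for (i in seq_along(contrasts)) {
    if (stale(f_scan[i], f_snps)) {
      logmsg("scan: CMH ", contrast_label(contrasts[[i]]))
      fwrite(cmh_scan(snps, design, contrasts[[i]]), f_scan[i], sep = "\t")
    }
  }

  # --- stage: null --------------------------------------------------------
  f_null_snps <- path("null_snps.tsv")
  f_null <- vapply(contrasts, function(ct)
    path(sprintf("null_cmh_%s.tsv", contrast_label(ct))), "")
  if (stale(c(f_null_snps, f_null), f_snps)) {
    logmsg("null: drift simulation (N = ", design$ne, ")")
    set.seed(seed + 1L)
    n_sim <- (config$null %||% list())$n_snps
    sim <- if (is.null(n_sim)) {
      simulate_null_experiment(design, base_snps = snps,
                               contrasts = contrasts)
    } else {
      idx <- sample.int(n_snps(snps), n_sim, replace = n_sim > n_snps(snps))
      simulate_null_experiment(design, base_snps = snps[idx],
                               contrasts = contrasts)
    }
    # null loci are identified by synthetic ids (resampling can duplicate
    # source positions)
    sim$snps$chrom <- rep("null", n_snps(sim$snps))
    sim$snps$pos <- seq_len(n_snps(sim$snps))
    write_snps(sim$snps, f_null_snps)
    for (i in seq_along(contrasts))
      fwrite(sim$scans[[contrast_label(contrasts[[i]])]], f_null[i],
             sep = "\t")
  }

  # --- stage: fdr ---------------------------------------------------------
  f_fdr <- path("fdr_report.tsv")
  if (stale(f_fdr, c(f_scan, f_null))) {
    logmsg("fdr: empirical FDR")
    rows <- lapply(seq_along(contrasts), function(i) {
      expp <- fread(f_scan[i])$p
      simp <- fread(f_null[i])$p
      thr <- empirical_threshold(simp, fdr_cfg$top_fraction %||% 1e-5)
      r1 <- empirical_fdr(expp, simp, thr)
      top_n <- min(fdr_cfg$top_n %||% 2000, sum(!is.na(expp)))
      r2 <- fdr_top_n(expp, simp, top_n)
      data.table(contrast = contrast_label(contrasts[[i]]),
                 rule = c("top_fraction", "top_n"),
                 threshold = c(r1$threshold, r2$threshold),
                 n_exp_below = c(r1$n_exp_below, r2$n_exp_below),
                 n_sim_below = c(r1$n_sim_below, r2$n_sim_below),
                 fdr = c(r1$fdr, r2$fdr))
    })
    fwrite(rbindlist(rows), f_fdr, sep = "\t")
  }

  # --- stage: candidates --------------------------------------------------
  f_cand <- vapply(contrasts, function(ct)
    path(sprintf("candidates_%s.tsv", contrast_label(ct))), "")
  for (i in seq_along(contrasts)) {
    if (stale(f_cand[i], f_scan[i])) {
      scan <- fread(f_scan[i])
      n_i <- min(n_cand, sum(!is.na(scan$p)))
      logmsg("candidates: top ", n_i, " of ", contrast_label(contrasts[[i]]))
      fwrite(top_candidates(scan, n_i), f_cand[i], sep = "\t")
    }
  }

  # --- stage: trajectories + classification ------------------------------
  tps <- unique(design$populations$timepoint)
  f_traj <- path("trajectories.tsv")
  f_class <- path("classification.tsv")
  have_bme <- all(c("B", "M", "E") %in% tps)
  if (have_bme && stale(c(f_traj, f_class), c(f_snps, f_cand, f_null_snps))) {
    logmsg("trajectories: orienting and classifying candidates")
    ori <- orient_selected_allele(snps, design, contrasts[[1]])
    traj <- selected_trajectories(snps, design, ori)
    fwrite(traj, f_traj, sep = "\t")
    null_snps <- read_snps(f_null_snps)
    null_traj <- trajectory_table(null_snps, design, "minor")
    null_me <- afc_summary(interval_afc(null_traj, "M", "E"))$afc
    cls <- lapply(seq_along(contrasts), function(i) {
      cand <- fread(f_cand[i])
      keyc <- snp_key(cand$chrom, cand$pos)
      tr <- traj[snp_key(chrom, pos) %in% keyc]
      bm <- afc_summary(interval_afc(tr, "B", "M"))
      me <- afc_summary(interval_afc(tr, "M", "E"))
      m <- merge(bm, me, by = c("chrom", "pos"), suffixes = c("_bm", "_me"))
      lab <- classify_trajectories(m$afc_bm, m$afc_me, null_late = null_me)
      data.table(contrast = contrast_label(contrasts[[i]]),
                 chrom = m$chrom, pos = m$pos,
                 afc_bm = m$afc_bm, afc_me = m$afc_me, label = as.character(lab))
    })
    fwrite(rbindlist(cls), f_class, sep = "\t")
  }

  # --- manifest -----------------------------------------------------------
  outs <- c(f_snps, f_scan, f_null_snps, f_null, f_fdr, f_cand)
  if (have_bme) outs <- c(outs, f_traj, f_class)
  if (file.exists(f_sync)) outs <- c(f_sync, truth_file, outs)
  outs <- outs[file.exists(outs)]
  manifest <- list(
    package = "erscan",
    version = as.character(utils::packageVersion("erscan")),
    seed = seed, config_digest = digest,
    files = lapply(stats::setNames(outs, basename(outs)), function(f)
      list(md5 = unname(tools::md5sum(f)),
           rows = length(readLines(f)))))
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  logmsg("done: ", length(outs), " outputs")
  invisible(manifest)
}
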