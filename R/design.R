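#' Experimental design of a replicated E&R experiment
#'
#' An `er_design` describes which sequenced population (pool) belongs to which
#' replicate and time point, at which generation it was sampled, and the
#' demographic constants of the experiment. The row order of `populations`
#' defines the column order of every count table in the package.
#'
#' @param populations data.frame with columns `pop` (unique population/sample
#'   label), `replicate` (integer), `timepoint` (label such as "B", "M", "E"),
#'   and `generation` (non-negative integer).
#' @param census_size census size of each experimental population.
#' @param pool_size number of (diploid) individuals pooled for sequencing.
#' @param ne effective population size used by drift simulations (haploid
#'   Wright-Fisher N).
#' @return An object of class `er_design`.
#' @seealso [default_design()], [validate_design()]
#' @export
er_design <- function(populations, census_size = 1000, pool_size = 500, ne = 200) {
  populations <- as.data.frame(populations, stringsAsFactors = FALSE)
  need <- c("pop", "replicate", "timepoint", "generation")
  if (!all(need %in% names(populations)))
    stop_param("`populations` needs columns: ", paste(need, collapse = ", "))
  populations$pop <- as.character(populations$pop)
  populations$timepoint <- as.character(populations$timepoint)
  populations$replicate <- as.integer(populations$replicate)
  populations$generation <- as.integer(populations$generation)
  d <- structure(
    list(populations = populations,
         census_size = census_size, pool_size = pool_size, ne = ne),
    class = "er_design")
  v <- validate_design(d)
  if (!v$ok) stop_param("invalid design: ", paste(v$errors, collapse = "; "))
  d
}

#' The three-replicate, three-time-point fly design
#'
#' Three replicate base populations sequenced at generation 0 (`B`), a middle
#' time point (`M`) sequenced at generation 15 for replicates 1-2 and
#' generation 23 for replicate 3, an end point (`E`) at generation 37 for all
#' replicates, and optionally one extra sample of replicate 1 at generation 27
#' (`F27`).
#'
#' @param include_f27 include the single generation-27 sample.
#' @inheritParams er_design
#' @return An `er_design`.
#' @export
default_design <- function(include_f27 = TRUE, census_size = 1000,
                           pool_size = 500, ne = 200) {
  pops <- data.frame(
    pop        = c("B1", "B2", "B3", "M1", "M2", "M3", "E1", "E2", "E3"),
    replicate  = c(1L, 2L, 3L, 1L, 2L, 3L, 1L, 2L, 3L),
    timepoint  = c("B", "B", "B", "M", "M", "M", "E", "E", "E"),
    generation = c(0L, 0L, 0L, 15L, 15L, 23L, 37L, 37L, 37L),
    stringsAsFactors = FALSE)
  if (include_f27)
    pops <- rbind(pops, data.frame(pop = "F27_1", replicate = 1L,
                                   timepoint = "F27", generation = 27L))
  er_design(pops, census_size = census_size, pool_size = pool_size, ne = ne)
}

#' Validate an experimental design
#'
#' Checks the structural invariants of an [er_design()]: unique population
#' labels, unique (replicate, timepoint) pairs, non-negative generations that
#' are consistent within a replicate, and positive demographic constants.
#'
#' @param design an `er_design`, or a path to a YAML design file.
#' @return list with `ok` (logical), `errors` (character) and a `summary`
#'   data.frame of time-point classes with their per-replicate generations.
#' @export
validate_design <- function(design) {
  if (is.character(design)) design <- read_design(design)
  p <- design$populations
  errors <- character()
  if (anyDuplicated(p$pop)) errors <- c(errors, "duplicated population labels")
  if (anyDuplicated(p[c("replicate", "timepoint")]))
    errors <- c(errors, "duplicated (replicate, timepoint) pairs")
  if (any(p$generation < 0, na.rm = TRUE) || anyNA(p$generation))
    errors <- c(errors, "generations must be non-negative integers")
  # within a replicate, a later-labelled time point must not go back in time:
  # time points ordered by their minimum generation must be non-decreasing
  for (r in unique(p$replicate)) {
    pr <- p[p$replicate == r, ]
    tp_order <- order(vapply(split(pr$generation, pr$timepoint), min, 0)[pr$timepoint])
    if (is.unsorted(pr$generation[tp_order]))
      errors <- c(errors, sprintf("generations decrease within replicate %s", r))
  }
  for (f in c("census_size", "pool_size", "ne"))
    if (!is.numeric(design[[f]]) || design[[f]] < 1)
      errors <- c(errors, sprintf("`%s` must be a positive number", f))
  summary <- do.call(rbind, lapply(split(p, p$timepoint), function(x)
    data.frame(timepoint = x$timepoint[1], n_replicates = nrow(x),
               generations = paste(x$generation[order(x$replicate)],
                                   collapse = "/"))))
  list(ok = length(errors) == 0L, errors = errors,
       summary = summary[order(summary$timepoint), ])
}

#' @export
print.er_design <- function(x, ...) {
  cat(sprintf("E&R design: %d populations, %d replicates\n",
              nrow(x$populations), length(unique(x$populations$replicate))))
  cat(sprintf("census %d, pool %d, Ne %s\n",
              x$census_size, x$pool_size, format(x$ne)))
  print(x$populations, row.names = FALSE)
  invisible(x)
}

#' Read / write a design as YAML
#'
#' @param path file path.
#' @return [read_design()] returns an `er_design`.
#' @export
read_design <- function(path) {
  y <- yaml::read_yaml(path)
  pops <- do.call(rbind, lapply(y$populations, as.data.frame))
  er_design(pops,
            census_size = y$census_size %||% 1000,
            pool_size = y$pool_size %||% 500,
            ne = y$ne %||% 200)
}

#' @param design an `er_design`.
#' @rdname read_design
#' @export
write_design <- function(design, path) {
  p <- design$populations
  yaml::write_yaml(list(
    census_size = design$census_size, pool_size = design$pool_size,
    ne = design$ne,
    populations = lapply(seq_len(nrow(p)), function(i) as.list(p[i, ]))), path)
  invisible(path)
}

# Pair populations of the two time points of a contrast, by replicate.
# Returns a data.frame(replicate, pop0, pop1, idx0, idx1, gen0, gen1) where
# idx* index into the design's population order (= count-table columns).
design_pairs <- function(design, contrast) {
  stopifnot(length(contrast) == 2L)
  p <- design$populations
  for (tp in contrast)
    if (!tp %in% p$timepoint)
      stop_param(sprintf("time point '%s' is not in the design", tp))
  a <- p[p$timepoint == contrast[1], ]
  b <- p[p$timepoint == contrast[2], ]
  reps <- intersect(a$replicate, b$replicate)
  if (length(reps) == 0L)
    stop_param("no replicate is sequenced at both contrast time points")
  data.frame(
    replicate = reps,
    pop0 = a$pop[match(reps, a$replicate)],
    pop1 = b$pop[match(reps, b$replicate)],
    idx0 = match(a$pop[match(reps, a$replicate)], p$pop),
    idx1 = match(b$pop[match(reps, b$replicate)], p$pop),
    gen0 = a$generation[match(reps, a$replicate)],
    gen1 = b$generation[match(reps, b$replicate)])
}

contrast_label <- function(contrast) paste(contrast, collapse = "-")
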