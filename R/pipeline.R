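#' Run the full pseudoextinction experiment over a set of matrices
#'
#' Orchestrates curation, the node recovery test in both modes, the
#' per-taxon shift test, pooled summaries, cross-dataset statistics and
#' the dataset jackknife. Every stochastic stage derives its seed from
#' the master seed and the unit of work (matrix, taxon, replicate), so a
#' rerun with the same inputs and seed reproduces the report exactly.
#'
#' @param matrices named list of `char_matrix` objects, or a directory
#'   containing matrix files (`.nex`/`.tnt`) with `<name>.partition.csv`
#'   sidecars and `<name>.json` configs naming the outgroup.
#' @param n_reps random replicates for both tests (500 at full scale).
#' @param settings a [search_settings()] profile.
#' @param alpha significance level.
#' @param seed master seed.
#' @param curate run the curation pipeline and drop non-includable
#'   matrices first.
#' @param taxon_shift run the per-taxon stage (the expensive one).
#' @param metric root-distance metric for the taxon shift test.
#' @param jackknife_resamples dataset jackknife resamples (0 = skip).
#' @return a list bundle: `curation`, `node_recovery` (per matrix, both
#'   modes), `aggregate` (pooled, both modes), `taxon_shifts`,
#'   `shift_summary`, `meta`, `jackknife`, `manifest`.
#' @export
run_experiment <- function(matrices, n_reps = 100L,
                           settings = desk_settings(), alpha = 0.05,
                           seed = 1L, curate = TRUE, taxon_shift = TRUE,
                           metric = "nodes", jackknife_resamples = 50L) {
  t0 <- Sys.time()
  if (is.character(matrices)) matrices <- read_matrix_dir(matrices)
  if (length(matrices) == 0L) stop("no input matrices")
  if (is.null(names(matrices)))
    names(matrices) <- sprintf("m%03d", seq_along(matrices))

  curation <- list()
  kept <- list()
  for (id in names(matrices)) {
    if (curate) {
      cur <- curate_matrix(matrices[[id]])
      curation[[id]] <- cur[c("reports", "inclusion")]
      if (!cur$inclusion$include) next
      kept[[id]] <- cur$matrix
    } else {
      kept[[id]] <- matrices[[id]]
    }
  }
  if (length(kept) == 0L) stop("no matrix passed the inclusion thresholds")

  modes <- c("fossilization", "inverse_fossilization")
  node_recovery <- list()
  for (id in names(kept)) {
    m <- kept[[id]]
    bench <- heuristic_search(m, settings,
                              seed = derive_seed(seed, id, "bench"))
    node_recovery[[id]] <- lapply(stats::setNames(modes, modes), function(md)
      run_node_recovery(m, md, n_reps = n_reps, settings = settings,
                        seed = derive_seed(seed, id, md), benchmark = bench))
  }
  aggregate <- lapply(stats::setNames(modes, modes), function(md)
    aggregate_node_recovery(lapply(node_recovery, `[[`, md)))

  taxon_shifts <- NULL
  shift_summary <- NULL
  meta <- list(expected_significant = alpha * length(kept))
  if (taxon_shift) {
    taxon_shifts <- lapply(stats::setNames(names(kept), names(kept)),
                           function(id)
      run_taxon_shift_all(kept[[id]], n_reps = n_reps, metric = metric,
                          settings = settings,
                          seed = derive_seed(seed, id, "shift")))
    flat <- unlist(taxon_shifts, recursive = FALSE)
    shift_summary <- list(
      fossilization = summarize_shifts(flat, "fossilization", alpha),
      random = summarize_shifts(flat, "random", alpha))
    meta <- c(meta, shift_meta_stats(shift_summary, alpha))
  }

  jackknife <- NULL
  if (jackknife_resamples > 0L) {
    jackknife <- lapply(stats::setNames(modes, modes), function(md)
      dataset_jackknife(lapply(node_recovery, `[[`, md),
                        n_resamples = jackknife_resamples, alpha = alpha,
                        seed = derive_seed(seed, "jack", md)))
  }

  list(curation = curation,
       node_recovery = node_recovery,
       aggregate = aggregate,
       taxon_shifts = taxon_shifts,
       shift_summary = shift_summary,
       meta = meta,
       jackknife = jackknife,
       manifest = list(seed = seed, n_reps = n_reps, settings = settings,
                       alpha = alpha, metric = metric,
                       n_input = length(matrices), n_included = length(kept),
                       included = names(kept),
                       elapsed_s = as.numeric(Sys.time() - t0, units = "secs")))
}

# binomial and G statistics over the pooled shift counts
shift_meta_stats <- function(shift_summary, alpha = 0.05) {
  fs <- shift_summary$fossilization
  rs <- shift_summary$random
  out <- list()
  if (fs$moved > 0) {
    out$binom_down_two_sided <- binomial_test(fs$moved_down, fs$moved, 0.5, "two")
    out$binom_down_one_sided <- binomial_test(fs$moved_down, fs$moved, 0.5, "one")
    out$down_fraction <- fs$moved_down / fs$moved
  }
  if (fs$significant > 0) {
    out$binom_sig_down <- binomial_test(fs$significant_down, fs$significant,
                                        0.5, "two")
    out$sig_down_fraction <- fs$significant_down / fs$significant
    out$binom_sig_excess <- binomial_test(fs$significant, fs$moved, alpha, "one")
  }
  if (fs$moved > 0 && rs$moved > 0 &&
      all(c(fs$moved_down, fs$moved_up, rs$moved_down, rs$moved_up) > 0)) {
    tab <- rbind(fossilization = c(down = fs$moved_down, up = fs$moved_up),
                 random = c(down = rs$moved_down, up = rs$moved_up))
    out$g_direction <- g_test(tab)
    out$direction_table <- tab
  }
  out
}

#' Read a directory of matrices with sidecar partitions and configs
#'
#' Loads every `.nex`/`.tnt` matrix in `dir`; each `<name>.<ext>` must be
#' accompanied by `<name>.partition.csv` (see [read_partition()]) and
#' `<name>.json` naming the outgroup. The counterpart of [write_suite()].
#'
#' @param dir directory path.
#' @return named list of `char_matrix` objects.
#' @export
read_matrix_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(nex|tnt)$", full.names = TRUE)
  if (length(files) == 0L) stop("no .nex/.tnt matrices in ", dir)
  out <- list()
  for (f in files) {
    base <- sub("\\.(nex|tnt)$", "", f)
    fmt <- if (grepl("\\.nex$", f)) "nexus" else "tnt"
    cfg_path <- paste0(base, ".json")
    if (!file.exists(cfg_path))
      stop("missing config ", cfg_path, " (must name the outgroup)")
    cfg <- jsonlite::read_json(cfg_path)
    out[[basename(base)]] <- read_matrix(f, fmt,
                                         partition = paste0(base, ".partition.csv"),
                                         outgroup = cfg$outgroup)
  }
  out
}

#' Write a synthetic suite to disk as analysis inputs
#'
#' Serializes every matrix of a [make_benchmark_suite()] result as a TNT
#' file with partition sidecar and outgroup config, so the pipeline can
#' be exercised from files exactly as it would be on compiled published
#' matrices.
#'
#' @param suite result of [make_benchmark_suite()].
#' @param dir output directory (created).
#' @param format `"tnt"` or `"nexus"`.
#' @return the directory, invisibly.
#' @export
write_suite <- function(suite, dir, format = "tnt") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "tnt") ".tnt" else ".nex"
  for (id in names(suite$matrices)) {
    m <- suite$matrices[[id]]
    base <- file.path(dir, id)
    write_matrix(m, paste0(base, ext), format,
                 partition_path = paste0(base, ".partition.csv"))
    jsonlite::write_json(list(outgroup = m$outgroup), paste0(base, ".json"),
                         auto_unbox = TRUE)
  }
  invisible(dir)
}
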