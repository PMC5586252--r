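# End-to-end orchestration: simulate -> ProP-PD processing -> motif
# discovery -> proteome scan -> report, with persisted intermediates and
# a run log, reproducible for a fixed configuration.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every stage parameter at its
#' default; any element can be overridden via `...` or by merging a
#' key=value file read with [read_pipeline_config()].
#'
#' @param ... Named overrides of default elements.
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    # synthetic stage
    n_proteins = 100L,
    length_min = 100L, length_max = 300L,
    n_intrinsic = 10L, n_phospho = 5L, n_decoy = 5L,
    baits = c("Bpa", "Bpg1"),
    tile_length = 16L, tile_overlap = 7L,
    enrichment_factor = 20, dispersion = 10,
    promiscuous_fraction = 0.05, base_mean = 0.2,
    # propd stage
    cutoff = 1L, cutoff_mode = "gt", max_bait_fraction = 0.5,
    # discovery stage
    alpha = 0.05, max_defined = 3L, correction = "bonferroni",
    # scan stage
    scan_mode = "n-rule", disorder = "off", min_disorder = NULL,
    # stage toggles
    run_simulate = TRUE, run_propd = TRUE, run_discover = TRUE,
    run_scan = TRUE,
    # optional external inputs (used when run_simulate = FALSE)
    proteome_fasta = NULL, counts_tsv = NULL
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) {
    stop("unknown config keys: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Read a key=value pipeline configuration file
#'
#' Plain-text `key = value` lines (comments start with `#`); values are
#' parsed as R literals where possible, otherwise kept as strings.
#'
#' @param path Path to the config file.
#' @return A `pipeline_config` with the file's overrides applied.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  over <- list()
  for (p in kv) {
    if (length(p) < 2) next
    key <- trimws(p[1])
    val <- trimws(paste(p[-1], collapse = "="))
    parsed <- tryCatch(eval(parse(text = val), envir = baseenv()),
                       error = function(e) val)
    over[[key]] <- parsed
  }
  do.call(pipeline_config, over)
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  writeLines(msg, con)
}

#' Run the full docking-motif pipeline
#'
#' Executes the configured stages in order -- synthetic-data generation
#' (proteome with planted ground truth, tiled library, simulated counts),
#' ProP-PD ligand-set construction, consensus-motif discovery, and the
#' proteome scan -- persisting each stage's outputs under the run
#' directory (`inputs/`, `intermediate/`, `results/`, `run.log`).
#' Identical configuration (including seed) gives identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param run_dir Output directory (created; must not exist or be empty).
#' @return Invisibly, a list with the run directory, the candidate table,
#'   the discovered motifs, the ligand sets and (when simulated) the
#'   truth table plus recall/precision summary.
#' @export
run_pipeline <- function(config = pipeline_config(), run_dir = tempfile("b56run")) {
  stopifnot(inherits(config, "pipeline_config"))
  dirs <- file.path(run_dir, c("inputs", "intermediate", "results"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  log <- file(file.path(run_dir, "run.log"), "w")
  on.exit(close(log))
  log_line(log, "b56motif ", as.character(utils::packageVersion("b56motif")))
  log_line(log, "seed = ", config$seed)

  truth <- NULL
  counts <- NULL
  proteome <- NULL

  if (isTRUE(config$run_simulate)) {
    t0 <- Sys.time()
    proteome <- generate_background_proteome(
      config$n_proteins, c(config$length_min, config$length_max),
      seed = config$seed)
    specs <- dplyr::bind_rows(
      if (config$n_intrinsic > 0)
        plant_spec("intrinsic", "L", "I", 2L, config$n_intrinsic),
      if (config$n_phospho > 0)
        plant_spec("phospho_responsive", "L", "V", 2L, config$n_phospho),
      if (config$n_decoy > 0)
        plant_spec("decoy", "L", "I", 2L, config$n_decoy)
    )
    planted <- plant_motifs(proteome, specs, seed = config$seed + 1L)
    proteome <- planted$proteins
    truth <- planted$truth
    tiles <- tile_library(proteome, config$tile_length,
                          config$tile_overlap)
    counts <- simulate_phage_counts(
      tiles, truth, config$baits,
      count_sim_config(config$tile_length, config$tile_overlap,
                       config$enrichment_factor, config$dispersion,
                       config$promiscuous_fraction, config$base_mean,
                       seed = config$seed + 2L))
    write_proteome_fasta(proteome, file.path(run_dir, "inputs",
                                             "proteome.fasta"))
    write_pipeline_tsv(truth, file.path(run_dir, "inputs", "truth.tsv"))
    write_pipeline_tsv(counts[, c("peptide", "bait", "count")],
                       file.path(run_dir, "inputs", "counts.tsv"))
    log_line(log, "simulate: ", nrow(proteome), " proteins, ",
             nrow(truth), " planted windows, ", nrow(counts),
             " count rows (",
             round(as.numeric(Sys.time() - t0, units = "secs"), 2), " s)")
  } else {
    if (is.null(config$proteome_fasta) ||
        !file.exists(config$proteome_fasta)) {
      stop("pipeline stage 'inputs' failed: missing proteome FASTA: ",
           config$proteome_fasta %||% "<unset>", call. = FALSE)
    }
    proteome <- read_proteome_fasta(config$proteome_fasta)
    if (!is.null(config$counts_tsv)) {
      if (!file.exists(config$counts_tsv)) {
        stop("pipeline stage 'inputs' failed: missing counts TSV: ",
             config$counts_tsv, call. = FALSE)
      }
      counts <- read_count_table(config$counts_tsv)
    }
    log_line(log, "inputs: ", nrow(proteome), " proteins loaded")
  }

  ligands <- NULL
  if (isTRUE(config$run_propd) && !is.null(counts)) {
    t0 <- Sys.time()
    ligands <- build_ligand_sets(
      counts, cutoff = config$cutoff, mode = config$cutoff_mode,
      max_bait_fraction = config$max_bait_fraction)
    write_pipeline_tsv(ligands, file.path(run_dir, "intermediate",
                                          "ligand_sets.tsv"))
    sets <- split(ligands$peptide, ligands$bait)
    if (length(sets) >= 2) {
      write_pipeline_tsv(
        dplyr::select(overlap_sets(sets), "region", "count"),
        file.path(run_dir, "results", "overlap.tsv"))
    }
    log_line(log, "propd: ", nrow(ligands), " ligand rows (",
             round(as.numeric(Sys.time() - t0, units = "secs"), 2), " s)")
  }

  motifs <- NULL
  if (isTRUE(config$run_discover) && !is.null(ligands) &&
      length(unique(ligands$peptide)) >= 5) {
    t0 <- Sys.time()
    motifs <- enumerate_candidate_motifs(
      unique(ligands$peptide), alpha = config$alpha,
      max_defined = config$max_defined,
      correction = config$correction)
    write_pipeline_tsv(utils::head(motifs, 50),
                       file.path(run_dir, "results", "motifs.tsv"))
    log_line(log, "discover: top motif ", motifs$pattern[1],
             " support ", motifs$support[1], " (",
             round(as.numeric(Sys.time() - t0, units = "secs"), 2), " s)")
  }

  candidates <- NULL
  if (isTRUE(config$run_scan)) {
    t0 <- Sys.time()
    candidates <- scan_proteome(
      proteome, mode = config$scan_mode, disorder = config$disorder,
      min_disorder = config$min_disorder)
    write_pipeline_tsv(candidates, file.path(run_dir, "results",
                                             "candidates.tsv"))
    log_line(log, "scan: ", nrow(candidates), " candidate rows (",
             round(as.numeric(Sys.time() - t0, units = "secs"), 2), " s)")
  }

  summary <- NULL
  if (!is.null(truth) && !is.null(candidates)) {
    planted <- truth[truth$target_class != "decoy", ]
    hit <- dplyr::inner_join(
      planted, candidates, by = c("protein", "start"))
    recall <- if (nrow(planted) > 0) nrow(hit) / nrow(planted) else NA
    decoys <- truth[truth$target_class == "decoy", ]
    leaked <- dplyr::inner_join(decoys, candidates,
                                by = c("protein", "start"))
    summary <- tibble::tibble(
      planted = nrow(planted), recovered = nrow(hit), recall = recall,
      decoys = nrow(decoys), decoy_leakage = nrow(leaked)
    )
    write_pipeline_tsv(summary, file.path(run_dir, "results",
                                          "recovery.tsv"))
    log_line(log, "recovery: recall = ", recall, ", decoy leakage = ",
             nrow(leaked))
  }

  invisible(list(run_dir = run_dir, candidates = candidates,
                 motifs = motifs, ligands = ligands, truth = truth,
                 summary = summary))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
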