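## Run configuration and the staged pipeline: simulate -> enrich -> train
## -> landscape -> evaluate. Every stage stamps its outputs with the
## manifest hash and refuses upstream artifacts from a different manifest.

MANIFEST_KEYS <- c("seed", "output_dir", "reads", "reference", "provider",
                   "landscape", "binning", "simulation", "model",
                   "calibration", "literature", "split")

#' Build and validate a run manifest
#'
#' A named list describing a full run: master seed, output directory,
#' input read files (or simulation parameters), embedding provider choice,
#' model settings, and calibration source. Unknown keys are rejected by
#' name. All stage seeds are derived deterministically from the master
#' seed.
#'
#' @param ... Manifest entries; recognised keys:
#'   `seed` (integer master seed), `output_dir`,
#'   `reads` (named list of read-file paths, `PRESORT` plus gates),
#'   `reference` (arguments to [reference_config()]),
#'   `provider` (`dim`, `seed` of the hash embedding provider),
#'   `landscape` (arguments to [plant_landscape()]),
#'   `binning` (arguments to [gate_binning_model()]),
#'   `simulation` (arguments to [simulation_config()]),
#'   `model` (`n_seeds`, optional per-gate overrides),
#'   `calibration` (`"preset"` or `"fitted"`),
#'   `literature` (arguments to [emit_literature_table()]),
#'   `split` (`fractions`).
#' @return Object of class `run_manifest`.
#' @export
run_manifest <- function(...) {
  m <- list(...)
  bad <- setdiff(names(m), MANIFEST_KEYS)
  if (length(bad)) {
    stop("invalid manifest key(s): ", paste(bad, collapse = ", "))
  }
  defaults <- list(seed = 1L, output_dir = "sortscape_run",
                   provider = list(dim = 64L, seed = 1L),
                   calibration = "preset",
                   model = list(n_seeds = 10L),
                   split = list(fractions = c(0.1, 0.1)))
  m <- utils::modifyList(defaults, m)
  m$seed <- as.integer(m$seed)
  stopifnot(m$calibration %in% c("preset", "fitted"))
  structure(m, class = "run_manifest")
}

#' Stable hash of a manifest
#'
#' @param manifest A [run_manifest()].
#' @return An 8-character hex string (FNV-1a over the canonical JSON
#'   serialization).
#' @export
manifest_hash <- function(manifest) {
  s <- as.character(jsonlite::toJSON(unclass(manifest), auto_unbox = TRUE,
                                     digits = NA))
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (as.double(h) * 16777619) %% 4294967296
  }
  sprintf("%08x", as.integer(h %% 2147483647))
}

manifest_cfg <- function(manifest) {
  do.call(reference_config, manifest$reference %||% list())
}

manifest_provider <- function(manifest) {
  hash_embedding_provider(dim = manifest$provider$dim %||% 64L,
                          seed = manifest$provider$seed %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_stage_manifest <- function(manifest, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- c(unclass(manifest), list(manifest_hash = manifest_hash(manifest)))
  jsonlite::write_json(out, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

check_stage_hash <- function(manifest, dir, stage) {
  p <- file.path(dir, "manifest.json")
  if (!file.exists(p)) {
    stop("missing upstream artifact for stage '", stage,
         "': run the previous stage first (", p, " not found)")
  }
  up <- jsonlite::read_json(p)
  if (!identical(up$manifest_hash, manifest_hash(manifest))) {
    stop("upstream manifest hash mismatch at stage '", stage,
         "': re-run upstream stages with this manifest")
  }
}

#' Pipeline stage: simulate a synthetic sort-seq dataset
#'
#' @param manifest A [run_manifest()].
#' @return Invisibly, the written file paths; reads, ground truth and a
#'   manifest copy land in `<output_dir>/simulate/`.
#' @export
run_simulate <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  cfg <- manifest_cfg(manifest)
  land <- do.call(plant_landscape,
                  c(list(cfg = cfg),
                    utils::modifyList(manifest$landscape %||% list(),
                                      list(seed = derive_seed(manifest$seed,
                                                              "landscape")))))
  binning <- do.call(gate_binning_model, manifest$binning %||% list())
  simcfg <- do.call(simulation_config,
                    utils::modifyList(manifest$simulation %||% list(),
                                      list(seed = derive_seed(manifest$seed,
                                                              "simulate"))))
  sim <- simulate_sort(land, binning, simcfg)
  dir <- file.path(manifest$output_dir, "simulate")
  paths <- write_sim_reads(sim, dir, format = "lines")
  write_stage_manifest(manifest, dir)
  invisible(paths)
}

#' Pipeline stage: enrichment ratios from reads
#'
#' Reads come from `manifest$reads` (external files) or, if absent, from
#' this manifest's simulate stage.
#'
#' @param manifest A [run_manifest()].
#' @return Invisibly, the [compute_enrichment()] table; TSVs (enrichment,
#'   counts, rejections) land in `<output_dir>/enrich/`.
#' @export
run_enrich <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  cfg <- manifest_cfg(manifest)
  if (!is.null(manifest$reads)) {
    reads <- lapply(manifest$reads, read_reads_file)
  } else {
    simdir <- file.path(manifest$output_dir, "simulate")
    check_stage_hash(manifest, simdir, "enrich")
    files <- stats::setNames(
      file.path(simdir, paste0(tolower(c(PRESORT, GATES)), ".txt")),
      c(PRESORT, GATES))
    reads <- lapply(files[file.exists(files)], read_reads_file)
    reads <- reads[vapply(reads, length, integer(1)) > 0L]
  }
  tbl <- count_variants(reads, cfg)
  enr <- compute_enrichment(tbl)
  dir <- file.path(manifest$output_dir, "enrich")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_enrichment_tsv(enr, tbl, file.path(dir, "enrichment.tsv"))
  utils::write.table(tbl$counts, file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_stage_manifest(manifest, dir)
  invisible(enr)
}

#' Pipeline stage: train the four gate ensembles
#'
#' @param manifest A [run_manifest()].
#' @param enr An enrichment table (defaults to re-reading the enrich
#'   stage's output).
#' @param exclude Variant ids to hold out of every training set (leakage
#'   control for calibration/validation variants).
#' @return Named list of `gate_ensemble` objects; the per-epoch loss log is
#'   written to `<output_dir>/train/training_log.tsv`.
#' @export
run_train <- function(manifest, enr = NULL, exclude = character()) {
  stopifnot(inherits(manifest, "run_manifest"))
  cfg <- manifest_cfg(manifest)
  provider <- manifest_provider(manifest)
  if (is.null(enr)) {
    edir <- file.path(manifest$output_dir, "enrich")
    check_stage_hash(manifest, edir, "train")
    enr <- utils::read.delim(file.path(edir, "enrichment.tsv"),
                             stringsAsFactors = FALSE)
  }
  if (length(exclude)) enr <- enr[!enr$variant_id %in% exclude, ]
  n_seeds <- manifest$model$n_seeds %||% 10L
  ensembles <- stats::setNames(lapply(GATES, function(g) {
    sub <- enr[enr$gate == g & is.finite(enr$log2_er), ]
    if (!nrow(sub)) stop("no training data for gate ", g)
    over <- manifest$model[[g]] %||% list()
    cfg_g <- do.call(model_config,
                     c(list(gate = g, n_seeds = n_seeds), over))
    feats <- build_feature_matrix(sub$variant_id, provider, cfg)
    train_gate_ensemble(feats, sub$log2_er, cfg_g,
                        seed = derive_seed(manifest$seed, paste0("train:", g)))
  }), GATES)
  dir <- file.path(manifest$output_dir, "train")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  log <- do.call(rbind, lapply(GATES, function(g) {
    do.call(rbind, lapply(seq_along(ensembles[[g]]$members), function(i) {
      l <- ensembles[[g]]$members[[i]]$net$losses
      if (!length(l)) return(NULL)
      data.frame(gate = g, member = i, epoch = seq_along(l), mse = l)
    }))
  }))
  if (!is.null(log)) {
    utils::write.table(log, file.path(dir, "training_log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  write_stage_manifest(manifest, dir)
  ensembles
}

#' Pipeline stage: assemble the landscape
#'
#' @param manifest A [run_manifest()].
#' @param ensembles The [run_train()] result.
#' @param coeffs A `calibration` (defaults to the published preset when
#'   `manifest$calibration == "preset"`; a fitted calibration must be
#'   supplied otherwise).
#' @param variants Variant ids to score (default: full universe).
#' @return The `landscape_table`, also written to
#'   `<output_dir>/landscape/landscape.tsv` (plus pair averages).
#' @export
run_landscape <- function(manifest, ensembles, coeffs = NULL,
                          variants = NULL) {
  stopifnot(inherits(manifest, "run_manifest"))
  if (is.null(coeffs)) {
    if (manifest$calibration != "preset") {
      stop("manifest requests a fitted calibration: pass coeffs")
    }
    coeffs <- calibration_preset()
  }
  cfg <- manifest_cfg(manifest)
  land <- build_landscape(ensembles, coeffs, variants = variants,
                          provider = manifest_provider(manifest), cfg = cfg)
  dir <- file.path(manifest$output_dir, "landscape")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_landscape_tsv(land, file.path(dir, "landscape.tsv"))
  write_stage_manifest(manifest, dir)
  land
}

#' Read or write manifests as YAML
#'
#' @param path YAML file path.
#' @param manifest A [run_manifest()] (for writing).
#' @return [read_manifest()] returns a `run_manifest`.
#' @export
read_manifest <- function(path) {
  do.call(run_manifest, yaml::read_yaml(path))
}

#' @rdname read_manifest
#' @export
write_manifest <- function(manifest, path) {
  yaml::write_yaml(unclass(manifest), path)
  invisible(path)
}
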