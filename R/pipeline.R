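#' @include synthetic.R preprocess.R model.R finetune.R interpret.R
NULL

.config_defaults <- list(
  resolution = 500000, window = 30, step = 20,
  chrom_pair = c("chr1", "chr2"),
  n_types = 4, n_bins = 50, n_chroms = 2,
  samples_per_combination = 100, min_combination_size = 2,
  library_size_min = 50000, library_size_max = 100000,
  template_total = 500000,
  conv_channels = c(16, 32, 64, 64), dense_units = c(64, 32),
  learning_rate = 0.001, epochs_max = 200, batch_size = 32,
  finetune_lr = 4e-4, finetune_epochs = 100,
  shap_samples = 64, shap_background = 100, top_fraction = 0.1,
  seed = 1)

#' Load a pipeline configuration
#'
#' Reads a YAML key-value file (or takes a named list) and merges it over
#' the package defaults. Unknown keys are kept verbatim.
#'
#' @param config Path to a YAML file, a named list, or `NULL` for pure
#'   defaults.
#' @return Named list with class `"decooc_config"`.
#' @export
loadConfig <- function(config = NULL) {
  user <- if (is.null(config)) list()
    else if (is.character(config)) yaml::read_yaml(config)
    else config
  out <- utils::modifyList(.config_defaults, user)
  structure(out, class = "decooc_config")
}

.cfg_model <- function(cfg) {
  modelConfig(n_cell_types = cfg$n_types, window_size = cfg$window,
              conv_channels = cfg$conv_channels,
              dense_units = cfg$dense_units,
              learning_rate = cfg$learning_rate,
              epochs_max = cfg$epochs_max, batch_size = cfg$batch_size,
              seed = cfg$seed)
}

.cfg_log <- function(cfg, stage) {
  .log_stage(stage, "seed", cfg$seed, "config",
             .digest_string(paste(names(cfg), vapply(cfg, function(x)
               paste(format(x), collapse = ","), character(1)),
               sep = "=")))
}

#' Simulate templates and bulk samples to disk
#'
#' Generates synthetic cell-type templates, enumerates the mixture design
#' (every combination of at least `min_combination_size` types), simulates
#' `samples_per_combination` bulk libraries per combination with random
#' compositions, and writes per-sample contact-pair files plus a
#' ground-truth manifest (`sample_id`, `cell_type`, `fraction`).
#'
#' @param config See [loadConfig()].
#' @param out_dir Output directory.
#' @return The manifest data.frame, invisibly.
#' @export
commandSimulate <- function(config = NULL, out_dir = "decooc_sim") {
  cfg <- loadConfig(config)
  .cfg_log(cfg, "simulate")
  dir.create(file.path(out_dir, "samples"), recursive = TRUE,
             showWarnings = FALSE)
  templates <- makeTemplates(cfg$n_types, n_bins = cfg$n_bins,
                             n_chroms = cfg$n_chroms,
                             structure_seed = cfg$seed,
                             total_per_chrom = cfg$template_total,
                             resolution = cfg$resolution)
  types <- names(templates)
  combos <- enumerateCombinations(types, cfg$min_combination_size)
  manifest <- list()
  idx <- 0L
  for (ci in seq_along(combos)) {
    for (si in seq_len(cfg$samples_per_combination)) {
      idx <- idx + 1L
      sid <- sprintf("sample_%04d", idx)
      seed_i <- .substream_seed(cfg$seed, sid)
      spec <- drawFractions(combos[[ci]], types, seed_i)
      m_sum <- drawLibrarySize(seed_i, cfg$library_size_min,
                               cfg$library_size_max)
      bulk <- synthesizeBulkFromPure(templates, spec, m_sum,
                                     seed = seed_i, sample_id = sid)
      writeContactPairs(bulk@contacts,
                        file.path(out_dir, "samples",
                                  paste0(sid, ".tsv")))
      manifest[[idx]] <- data.frame(sample_id = sid, cell_type = types,
                                    fraction = unname(fractions(spec)))
    }
  }
  manifest <- do.call(rbind, manifest)
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

# read simulated samples back into BulkSample objects
.read_samples <- function(cfg, sim_dir, ids = NULL) {
  manifest <- utils::read.table(file.path(sim_dir, "manifest.tsv"),
                                header = TRUE, sep = "\t")
  if (is.null(ids)) ids <- unique(manifest$sample_id)
  lapply(ids, function(sid) {
    rows <- manifest[manifest$sample_id == sid, ]
    spec <- new("MixtureSpec", cellTypes = rows$cell_type,
                fractions = rows$fraction, seed = NA_integer_)
    contacts <- readContactPairs(
      file.path(sim_dir, "samples", paste0(sid, ".tsv")),
      resolution = cfg$resolution, coords = "bin")
    new("BulkSample", spec = spec, contacts = contacts,
        provenance = numeric(0), sampleId = sid)
  })
}

.sim_dataset <- function(cfg, sim_dir, ids = NULL) {
  samples <- .read_samples(cfg, sim_dir, ids)
  buildDataset(samples, chrom_pair = cfg$chrom_pair, n_bins = cfg$n_bins,
               window = cfg$window, step = cfg$step)
}

#' Train the cross-validated ensemble from simulated samples
#'
#' @param config See [loadConfig()].
#' @param sim_dir Directory written by [commandSimulate()].
#' @param checkpoint Output checkpoint path (an RDS container holding the
#'   ensemble with its config embedded).
#' @return The [CVEnsemble-class], invisibly.
#' @export
commandTrain <- function(config = NULL, sim_dir = "decooc_sim",
                         checkpoint = "decooc_model.rds") {
  cfg <- loadConfig(config)
  .cfg_log(cfg, "train")
  dataset <- .sim_dataset(cfg, sim_dir)
  ensemble <- trainEnsemble(dataset, .cfg_model(cfg), verbose = TRUE)
  saveRDS(list(ensemble = ensemble, config = cfg,
               dataset_digest = .digest_string(dataset@sampleId)),
          checkpoint)
  cv <- vapply(ensemble@models, function(m) m@history$best_val_rmse,
               numeric(1))
  .log_stage("train", "CV val RMSE per fold:",
             paste(signif(cv, 4), collapse = ", "))
  invisible(ensemble)
}

#' Predict sample compositions from a checkpoint
#'
#' @param config See [loadConfig()].
#' @param checkpoint Checkpoint from [commandTrain()] or
#'   [commandFinetune()].
#' @param sim_dir Directory of samples to predict.
#' @param out Output TSV path (`sample_id`, `cell_type`, `fraction`).
#' @return The prediction table, invisibly.
#' @export
commandPredict <- function(config = NULL, checkpoint = "decooc_model.rds",
                           sim_dir = "decooc_sim",
                           out = "decooc_predictions.tsv") {
  cfg <- loadConfig(config)
  .cfg_log(cfg, "predict")
  ck <- readRDS(checkpoint)
  dataset <- .sim_dataset(cfg, sim_dir)
  preds <- predictDataset(ck$ensemble, dataset)
  tab <- do.call(rbind, lapply(names(preds), function(sid)
    data.frame(sample_id = sid, cell_type = cellTypes(preds[[sid]]),
               fraction = round(unname(fractions(preds[[sid]])), 4))))
  utils::write.table(tab, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tab)
}

#' Fine-tune a pretrained checkpoint on real labelled samples
#'
#' @param config See [loadConfig()].
#' @param checkpoint Pretrained checkpoint.
#' @param real_dir Directory holding the real samples (same layout as
#'   [commandSimulate()]: `samples/` plus a `manifest.tsv` of reference
#'   fractions).
#' @param out Output checkpoint path.
#' @return The fine-tuned [CVEnsemble-class], invisibly.
#' @export
commandFinetune <- function(config = NULL, checkpoint = "decooc_model.rds",
                            real_dir = "decooc_real",
                            out = "decooc_finetuned.rds") {
  cfg <- loadConfig(config)
  .cfg_log(cfg, "finetune")
  ck <- readRDS(checkpoint)
  if (!file.exists(file.path(real_dir, "manifest.tsv")))
    stop("missing reference fractions: ", file.path(real_dir, "manifest.tsv"))
  dataset <- .sim_dataset(cfg, real_dir)
  tuned <- finetuneEnsemble(ck$ensemble, dataset, lr = cfg$finetune_lr,
                            epochs = cfg$finetune_epochs, verbose = TRUE)
  saveRDS(list(ensemble = tuned, config = cfg), out)
  invisible(tuned)
}

#' SHAP attribution from a checkpoint
#'
#' Explains the given samples against the training background, writes the
#' correlation report with observed/expected Hi-C and the high-SHAP BED.
#'
#' @param config See [loadConfig()].
#' @param checkpoint Trained checkpoint.
#' @param sim_dir Directory of samples to explain (the background is drawn
#'   from the same set).
#' @param out_prefix Prefix for the output files.
#' @param n_explain Number of tensors to explain (default 10).
#' @return List with the [ShapMap-class], correlation table and regions,
#'   invisibly.
#' @export
commandExplain <- function(config = NULL, checkpoint = "decooc_model.rds",
                           sim_dir = "decooc_sim",
                           out_prefix = "decooc_shap", n_explain = 10) {
  cfg <- loadConfig(config)
  .cfg_log(cfg, "explain")
  ck <- readRDS(checkpoint)
  dataset <- .sim_dataset(cfg, sim_dir)
  idx <- seq_len(min(n_explain, length(dataset)))
  shap <- shapAttribute(ck$ensemble, subsetDataset(dataset, idx), dataset,
                        n_samples = cfg$shap_samples,
                        background_cap = cfg$shap_background,
                        seed = cfg$seed)
  samples <- .read_samples(cfg, sim_dir,
                           unique(dataset@sampleId[idx]))
  oe <- list()
  for (ch in cfg$chrom_pair) {
    pooled <- do.call(rbind, lapply(samples, records))
    oe[[ch]] <- observedExpected(
      toMatrix(contactList(pooled, cfg$resolution), ch, cfg$n_bins))
  }
  corr <- shapHicCorrelation(shap, oe)
  regions <- highShapRegions(shap, top_fraction = cfg$top_fraction)
  writeBedRegions(regions, cfg$resolution,
                  paste0(out_prefix, "_regions.bed"))
  utils::write.table(corr, paste0(out_prefix, "_correlation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(shap = shap, correlation = corr, regions = regions))
}

#' Evaluate predictions against a ground-truth manifest
#'
#' @param config See [loadConfig()].
#' @param manifest Path to a ground-truth manifest TSV.
#' @param predictions Path to a prediction TSV from [commandPredict()].
#' @param out Output TSV path for the per-sample metric table.
#' @return List of per-sample and per-cell-type metric tables, invisibly.
#' @export
commandEvaluate <- function(config = NULL,
                            manifest = "decooc_sim/manifest.tsv",
                            predictions = "decooc_predictions.tsv",
                            out = "decooc_metrics.tsv") {
  cfg <- loadConfig(config)
  .cfg_log(cfg, "evaluate")
  to_wide <- function(path) {
    long <- utils::read.table(path, header = TRUE, sep = "\t")
    ids <- unique(long$sample_id)
    types <- unique(long$cell_type)
    m <- matrix(0, length(ids), length(types),
                dimnames = list(ids, types))
    m[cbind(match(long$sample_id, ids), match(long$cell_type, types))] <-
      long$fraction
    m
  }
  yt <- to_wide(manifest)
  yp <- to_wide(predictions)
  common <- intersect(rownames(yt), rownames(yp))
  yt <- yt[common, , drop = FALSE]
  yp <- yp[common, colnames(yt), drop = FALSE]
  per_sample <- evaluateFractions(yt, yp, group_by = "sample")
  per_type <- evaluateFractions(yt, yp, group_by = "cell_type")
  utils::write.table(per_sample, out, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  .log_stage("evaluate", sprintf(
    "%d samples: mean RMSE %.4f, mean modified CCC %.4f", nrow(per_sample),
    mean(per_sample$rmse), mean(per_sample$modified_ccc)))
  invisible(list(per_sample = per_sample, per_cell_type = per_type))
}
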