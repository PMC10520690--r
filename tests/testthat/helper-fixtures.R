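# Shared fixtures. Everything is generated in code; the heavyweight study
# (templates -> mixtures -> five-fold ensemble) is memoised so the
# acceptance tests share one training run.

.fixture_env <- new.env(parent = emptyenv())

# tiny two-type templates for fast unit tests
tiny_templates <- function(k = 2, n_bins = 36, seed = 42) {
  makeTemplates(k, n_bins = n_bins, n_chroms = 2, structure_seed = seed,
                total_per_chrom = 2e4)
}

# simulate a set of bulk samples over the full combination design
make_mixture_samples <- function(templates, n, seed_base = 1000,
                                 lib_range = c(5e4, 1e5)) {
  combos <- enumerateCombinations(length(templates), 2)
  lapply(seq_len(n), function(i) {
    seed <- seed_base + i
    spec <- drawFractions(combos[[(i %% length(combos)) + 1L]],
                          names(templates), seed)
    m <- drawLibrarySize(seed, lib_range[1], lib_range[2])
    synthesizeBulkFromPure(templates, spec, m, seed = seed,
                           sample_id = sprintf("s%04d", i))
  })
}

# The desk-scale deconvolution study: 4 synthetic cell types on two
# 50-bin chromosomes, 300 training and 60 held-out mixtures over the 11
# combinations, five-fold CV ensemble (8-16-16-16 channels, <= 100
# epochs). Trained once per session.
deconv_study <- function() {
  if (!is.null(.fixture_env$study)) return(.fixture_env$study)
  tpl <- makeTemplates(4, n_bins = 50, n_chroms = 2, structure_seed = 1)
  samples <- make_mixture_samples(tpl, 360)
  ds <- buildDataset(samples, c("chr1", "chr2"), n_bins = 50)
  ids <- unique(ds@sampleId)
  cfg <- modelConfig(4, conv_channels = c(8, 16, 16, 16),
                     epochs_max = 100, seed = 11)
  ens <- trainEnsemble(subsetDataset(ds, ids[1:300]), cfg)
  .fixture_env$study <- list(
    templates = tpl, dataset = ds, ids = ids, config = cfg,
    train_ds = subsetDataset(ds, ids[1:300]),
    test_ds = subsetDataset(ds, ids[301:360]),
    ensemble = ens)
  .fixture_env$study
}

# per-sample held-out metrics for an ensemble/model
heldout_metrics <- function(model, dataset) {
  ids <- unique(dataset@sampleId)
  t(vapply(ids, function(id) {
    sub <- subsetDataset(dataset, id)
    p <- fractions(predictSample(model, sub))
    y <- sub@labels[1, ]
    c(rmse = rmse(y, p), mccc = modifiedCCC(y, p))
  }, c(rmse = 0, mccc = 0)))
}

# a DeconvModel whose output is a fixed constant vector (all weights zero,
# output bias = log(p)), for testing prediction aggregation contracts
constant_model <- function(p, window = 16) {
  cfg <- modelConfig(length(p), window_size = window,
                     conv_channels = c(2, 2, 2, 2), dense_units = c(4, 4))
  m <- buildModel(cfg)
  m@params$Wc <- lapply(m@params$Wc, function(w) w * 0)
  m@params$bc <- lapply(m@params$bc, function(b) b * 0)
  m@params$Wd <- lapply(m@params$Wd, function(w) w * 0)
  m@params$bd <- lapply(m@params$bd, function(b) b * 0)
  m@params$bd[[3]] <- log(p)
  m
}
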