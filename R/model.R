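#' @include AllClasses.R utils.R
NULL

#' Model hyperparameter configuration
#'
#' Assembles the hyperparameters of the deconvolution CNN: four convolution
#' layers (tanh, 2x2 max-pooling after the first three), two hidden dense
#' layers (tanh) and a K-unit output layer. Training minimises MSE with
#' Adam, decays the learning rate on a validation-RMSE plateau (patience 4,
#' factor 0.98) and stops early when validation RMSE no longer improves.
#'
#' @param n_cell_types Number of output units K.
#' @param window_size Window side length in bins (default 30; the input
#'   tensor is `2 * window_size x window_size`). Must be at least 8 so the
#'   map survives three pooling stages.
#' @param conv_channels Four conv channel counts (default 16, 32, 64, 64).
#' @param kernel_size Conv kernel side (default 3).
#' @param dense_units Two hidden dense widths (default 64, 32).
#' @param output_activation `"softmax"` (default; enforces the simplex) or
#'   `"linear"` (renormalised at prediction time).
#' @param learning_rate Adam learning rate (default 0.001).
#' @param scheduler_patience,scheduler_factor Learning-rate plateau decay
#'   (defaults 4 and 0.98).
#' @param early_stopping_patience,early_stopping_min_delta Early-stopping
#'   controls (defaults 20 epochs, 1e-5).
#' @param epochs_max Maximum training epochs (default 200).
#' @param batch_size Minibatch size (default 32).
#' @param seed Master seed for initialisation, shuffling and fold
#'   assignment.
#' @return Named list of class `"deconv_config"`.
#' @export
modelConfig <- function(n_cell_types, window_size = 30,
                        conv_channels = c(16, 32, 64, 64),
                        kernel_size = 3, dense_units = c(64, 32),
                        output_activation = c("softmax", "linear"),
                        learning_rate = 0.001, scheduler_patience = 4,
                        scheduler_factor = 0.98,
                        early_stopping_patience = 20,
                        early_stopping_min_delta = 1e-5, epochs_max = 200,
                        batch_size = 32, seed = 1) {
  output_activation <- match.arg(output_activation)
  stopifnot(length(conv_channels) == 4, length(dense_units) == 2,
            scheduler_factor > 0, scheduler_factor < 1, n_cell_types >= 1)
  if (window_size %/% 8 < 1)
    stop("window_size must be at least 8 bins to pass three 2x2 pooling stages")
  structure(list(
    nCellTypes = as.integer(n_cell_types),
    windowSize = as.integer(window_size),
    convChannels = as.integer(conv_channels),
    kernelSize = as.integer(kernel_size),
    denseUnits = as.integer(dense_units),
    activation = "tanh",
    outputActivation = output_activation,
    learningRate = learning_rate,
    schedulerPatience = as.integer(scheduler_patience),
    schedulerFactor = scheduler_factor,
    earlyStoppingPatience = as.integer(early_stopping_patience),
    earlyStoppingMinDelta = early_stopping_min_delta,
    epochsMax = as.integer(epochs_max),
    batchSize = as.integer(batch_size),
    seed = as.integer(seed)), class = "deconv_config")
}

# native-layer view of a config
.cnn_cfg <- function(config) {
  list(H = 2L * config$windowSize, W = config$windowSize,
       K = config$nCellTypes, kernel = config$kernelSize,
       channels = config$convChannels, dense = config$denseUnits,
       softmax = identical(config$outputActivation, "softmax"))
}

#' Build an untrained deconvolution model
#'
#' Initialises the network with Glorot-uniform weights, deterministically
#' given the config seed.
#'
#' @param config A config from [modelConfig()].
#' @return A [DeconvModel-class].
#' @export
buildModel <- function(config) {
  params <- .cnn_init(.cnn_cfg(config), config$seed)
  new("DeconvModel", config = unclass(config), params = params)
}

#' Number of trainable parameters of a model
#'
#' @param model A [DeconvModel-class].
#' @return Integer count; conv parameters are excluded while the conv stack
#'   is frozen.
#' @export
trainableParams <- function(model) {
  count <- function(lst) sum(vapply(lst, length, numeric(1)))
  conv <- count(model@params$Wc) + count(model@params$bc)
  dense <- count(model@params$Wd) + count(model@params$bd)
  as.integer(if (isTRUE(model@frozenConv)) dense else conv + dense)
}

.dataset_tensors <- function(x) {
  if (is(x, "DeconvDataset")) return(x@tensors)
  if (is.array(x) && length(dim(x)) == 3) return(x)
  if (is.matrix(x)) return(array(x, dim = c(dim(x), 1)))
  if (is.list(x))
    return(array(unlist(x), dim = c(nrow(x[[1]]), ncol(x[[1]]),
                                    length(x))))
  stop("cannot interpret tensors: supply a DeconvDataset, array or list")
}

# shared core of the per-model / per-ensemble prediction methods
.predict_models <- function(models, tensors, cell_types) {
  X <- .dataset_tensors(tensors)
  preds <- lapply(models, function(m)
    .cnn_predict(m@params, .cnn_cfg(m@config), X))
  p <- Reduce(`+`, lapply(preds, colMeans)) / length(preds)
  p[p < 0] <- 0
  p <- if (sum(p) > 0) p / sum(p) else rep(1 / length(p), length(p))
  new("MixtureSpec", cellTypes = cell_types, fractions = unname(p),
      seed = NA_integer_)
}

#' Predict a sample's composition
#'
#' Averages the per-tensor network outputs over all tensors of the sample
#' (and over all fold models when an ensemble is given), then renormalises
#' onto the simplex.
#'
#' @param object A [DeconvModel-class] or [CVEnsemble-class].
#' @param tensors A [DeconvDataset-class], a `(2w, w, n)` array, a single
#'   matrix, or a list of matrices -- the tensors of one sample.
#' @param ... Unused.
#' @return A [MixtureSpec-class] prediction.
#' @export
setGeneric("predictSample", function(object, tensors, ...)
  standardGeneric("predictSample"))

#' @rdname predictSample
setMethod("predictSample", "DeconvModel", function(object, tensors, ...) {
  ct <- paste0("type", seq_len(object@config$nCellTypes))
  .predict_models(list(object), tensors, ct)
})

#' @rdname predictSample
setMethod("predictSample", "CVEnsemble", function(object, tensors, ...) {
  .predict_models(object@models, tensors, cellTypes(object))
})

#' Predict compositions for every sample of a dataset
#'
#' @param object A [DeconvModel-class] or [CVEnsemble-class].
#' @param dataset A [DeconvDataset-class].
#' @return Named list of [MixtureSpec-class], one per unique sample id.
#' @export
predictDataset <- function(object, dataset) {
  ids <- unique(dataset@sampleId)
  out <- lapply(ids, function(id)
    predictSample(object, subsetDataset(dataset, id)))
  names(out) <- ids
  out
}

# train one model on explicit train/validation tensor sets
.train_one <- function(config, Xtr, Ytr, Xval, Yval, seed,
                       train_conv = TRUE, params = NULL, lr = NULL,
                       epochs = NULL, es_patience = NULL) {
  if (is.null(params)) params <- .cnn_init(.cnn_cfg(config), seed)
  opt <- list(lr = if (is.null(lr)) config$learningRate else lr,
              epochs = if (is.null(epochs)) config$epochsMax else epochs,
              batch = config$batchSize,
              sched_patience = config$schedulerPatience,
              sched_factor = config$schedulerFactor,
              es_patience = if (is.null(es_patience))
                config$earlyStoppingPatience else es_patience,
              es_min_delta = config$earlyStoppingMinDelta,
              train_conv = train_conv, seed = seed)
  .cnn_train(params, .cnn_cfg(config), Xtr, Ytr, Xval, Yval, opt)
}

#' Train the five-fold cross-validated ensemble
#'
#' Splits samples (not tensors: all tensors of a sample stay on one side,
#' preventing leakage) into `n_folds` folds, trains one network per fold on
#' the remaining folds with the fold held out for validation, and returns
#' the ensemble of per-fold models together with the split.
#'
#' @param dataset A [DeconvDataset-class].
#' @param config A config from [modelConfig()].
#' @param n_folds Number of folds (default 5).
#' @param verbose Log per-fold progress.
#' @return A [CVEnsemble-class].
#' @export
trainEnsemble <- function(dataset, config, n_folds = 5, verbose = FALSE) {
  ids <- unique(dataset@sampleId)
  if (length(ids) < n_folds)
    stop("need at least as many samples as folds")
  shuffled <- .with_substream(config$seed, "folds", sample(ids))
  fold_of <- stats::setNames(rep(seq_len(n_folds),
                                 length.out = length(shuffled)), shuffled)
  models <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    val_ids <- names(fold_of)[fold_of == f]
    tr <- subsetDataset(dataset, setdiff(ids, val_ids))
    va <- subsetDataset(dataset, val_ids)
    fit <- .train_one(config, tr@tensors, tr@labels, va@tensors, va@labels,
                      seed = .substream_seed(config$seed,
                                             paste0("fold", f)))
    models[[f]] <- new("DeconvModel", config = unclass(config),
                       params = fit$params, foldId = as.integer(f),
                       history = fit[c("train_loss", "val_rmse", "lr",
                                       "best_epoch", "best_val_rmse")])
    if (verbose)
      .log_stage("train", sprintf(
        "fold %d/%d: %d epochs, best val RMSE %.4f", f, n_folds,
        length(fit$train_loss), fit$best_val_rmse))
  }
  new("CVEnsemble", models = models, splitAssignment = fold_of,
      cellTypes = cellTypes(dataset))
}

#' Validation metric as a function of training-set size
#'
#' Retrains a single model at each requested number of training samples
#' against one fixed validation set (the last 20% of samples), tracing how
#' quickly performance saturates with design size.
#'
#' @param dataset A [DeconvDataset-class].
#' @param sizes Integer vector of training-set sizes (in samples).
#' @param config A config from [modelConfig()].
#' @param verbose Log progress.
#' @return data.frame with columns `size` and `val_rmse`.
#' @export
learningCurve <- function(dataset, sizes, config, verbose = FALSE) {
  ids <- unique(dataset@sampleId)
  n_val <- max(1L, floor(0.2 * length(ids)))
  val_ids <- ids[(length(ids) - n_val + 1L):length(ids)]
  train_ids <- setdiff(ids, val_ids)
  va <- subsetDataset(dataset, val_ids)
  stopifnot(all(sizes <= length(train_ids)))
  res <- vapply(sizes, function(sz) {
    tr <- subsetDataset(dataset, train_ids[seq_len(sz)])
    fit <- .train_one(config, tr@tensors, tr@labels, va@tensors, va@labels,
                      seed = .substream_seed(config$seed,
                                             paste0("size", sz)))
    if (verbose) .log_stage("curve", sz, "samples -> val RMSE",
                            signif(fit$best_val_rmse, 4))
    fit$best_val_rmse
  }, numeric(1))
  data.frame(size = as.integer(sizes), val_rmse = res)
}
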