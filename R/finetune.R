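#' @include model.R
NULL

#' Freeze / unfreeze the convolutional stack
#'
#' `freezeConv` marks the four convolution layers non-trainable so that
#' subsequent fine-tuning updates only the dense layers; `unfreezeConv`
#' reverts it.
#'
#' @param model A [DeconvModel-class].
#' @return The model with the freeze flag toggled.
#' @export
freezeConv <- function(model) {
  model@frozenConv <- TRUE
  model
}

#' @rdname freezeConv
#' @export
unfreezeConv <- function(model) {
  model@frozenConv <- FALSE
  model
}

#' Fine-tune a pretrained ensemble on labelled real samples
#'
#' Transfer-learning adaptation: in each of the fold models the
#' convolutional stack is frozen and only the dense layers are retrained on
#' the real samples at a small learning rate (default 4e-4). All five fold
#' models are fine-tuned independently on the same samples; predictions of
#' the fine-tuned ensemble are their average.
#'
#' The real samples' reference fractions serve as labels. Because a few
#' dense layers can memorise a handful of samples within tens of epochs,
#' a fraction of the fine-tune samples (default 25%, at least one sample
#' when four or more are supplied) is held out as a validation set: early
#' stopping and the plateau scheduler monitor its RMSE and the best-epoch
#' weights are restored. With fewer than four samples (or
#' `val_fraction = 0`) the training RMSE is monitored instead.
#'
#' @param ensemble A pretrained [CVEnsemble-class].
#' @param dataset A labelled [DeconvDataset-class] of the real samples
#'   (labels = reference fractions).
#' @param lr Fine-tuning learning rate (default 0.0004).
#' @param epochs Maximum fine-tuning epochs (default 100).
#' @param patience Early-stopping patience (default 10).
#' @param val_fraction Fraction of fine-tune samples held out to monitor
#'   early stopping (default 0.25).
#' @param verbose Log per-model progress.
#' @return A [CVEnsemble-class] of fine-tuned models.
#' @export
finetuneEnsemble <- function(ensemble, dataset, lr = 4e-4, epochs = 100,
                             patience = 10, val_fraction = 0.25,
                             verbose = FALSE) {
  if (nrow(dataset@labels) == 0)
    stop("real samples must carry reference fractions as labels")
  if (!identical(cellTypes(dataset), cellTypes(ensemble)))
    stop("cell types of dataset and ensemble disagree")
  ids <- unique(dataset@sampleId)
  n_val <- if (val_fraction > 0 && length(ids) >= 4)
    ceiling(val_fraction * length(ids)) else 0L
  if (n_val > 0) {
    val_ids <- ids[(length(ids) - n_val + 1L):length(ids)]
    tr <- subsetDataset(dataset, setdiff(ids, val_ids))
    va <- subsetDataset(dataset, val_ids)
  } else {
    tr <- va <- dataset
  }
  models <- lapply(seq_along(ensemble@models), function(i) {
    m <- freezeConv(ensemble@models[[i]])
    fit <- .train_one(m@config, tr@tensors, tr@labels,
                      va@tensors, va@labels,
                      seed = .substream_seed(m@config$seed,
                                             paste0("finetune", i)),
                      train_conv = FALSE, params = m@params, lr = lr,
                      epochs = epochs, es_patience = patience)
    if (verbose)
      .log_stage("finetune", sprintf("model %d: %d epochs, train RMSE %.4f",
                                     i, length(fit$train_loss),
                                     fit$best_val_rmse))
    new("DeconvModel", config = m@config, params = fit$params,
        foldId = m@foldId,
        history = fit[c("train_loss", "val_rmse", "lr", "best_epoch",
                        "best_val_rmse")],
        frozenConv = TRUE)
  })
  new("CVEnsemble", models = models,
      splitAssignment = ensemble@splitAssignment,
      cellTypes = cellTypes(ensemble))
}

#' Predict with a fine-tuned ensemble
#'
#' Mean of the fine-tuned fold models' sample-level predictions,
#' renormalised onto the simplex. Identical to [predictSample()] on the
#' ensemble; provided as the named counterpart of [finetuneEnsemble()].
#'
#' @param ensemble A fine-tuned [CVEnsemble-class].
#' @param tensors The sample's tensors (see [predictSample()]).
#' @return A [MixtureSpec-class].
#' @export
predictFinetuned <- function(ensemble, tensors) {
  predictSample(ensemble, tensors)
}

#' Apply a smooth multiplicative batch effect to templates
#'
#' Emulates the systematic protocol differences between the training
#' domain (e.g. cultured cell lines) and real tissue by multiplying every
#' template entry `(i, j)` by a smooth positional gain composed of a
#' distance-decay shift `(1 + |i - j|)^-decay_shift` (library preparation
#' changes the short- versus long-range contact ratio) and a low-frequency
#' sinusoidal gain in the position `i + j` with log2-amplitude `strength`.
#' Both components are symmetric but not separable into per-bin factors,
#' so the effect survives matrix balancing -- a purely per-bin coverage
#' bias would be removed by it.
#'
#' @param templates List of [CellTypeTemplate-class].
#' @param strength Amplitude of the positional log2 gain (default 0.5).
#' @param decay_shift Added distance-decay exponent (default 0.15).
#' @param seed Integer seed for the gain's random phase.
#' @return Perturbed templates of the same shape.
#' @export
perturbTemplates <- function(templates, strength = 0.5, decay_shift = 0.15,
                             seed = 1) {
  .with_substream(seed, "batch_effect", {
    lapply(templates, function(tpl) {
      tpl@matrices <- lapply(tpl@matrices, function(m) {
        n <- nBins(m)
        phase <- stats::runif(1, 0, 2 * pi)
        idx <- seq_len(n)
        pos_gain <- 2^(strength *
                         sin(2 * pi * outer(idx, idx, "+") / (2 * n) +
                             phase))
        decay_gain <- (1 + abs(outer(idx, idx, "-")))^(-decay_shift)
        v <- round(contactValues(m) * pos_gain * decay_gain)
        contactMatrix(v, chrom = chrom(m), resolution = resolution(m))
      })
      tpl@totalContacts <- sum(vapply(tpl@matrices, function(m) {
        v <- contactValues(m)
        sum(v[upper.tri(v, diag = TRUE)])
      }, numeric(1)))
      tpl
    })
  })
}
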