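test_that("model construction is deterministic and simplex-valued", {
  cfg <- modelConfig(4, window_size = 16, conv_channels = c(4, 8, 8, 8),
                     dense_units = c(16, 8), seed = 3)
  m1 <- buildModel(cfg)
  m2 <- buildModel(cfg)
  expect_identical(m1@params, m2@params)
  m3 <- buildModel(modelConfig(4, window_size = 16,
                               conv_channels = c(4, 8, 8, 8),
                               dense_units = c(16, 8), seed = 4))
  expect_false(identical(m1@params, m3@params))
  # forward pass of zeros: finite simplex output
  x <- matrix(0, 32, 16)
  p <- fractions(predictSample(m1, x))
  expect_true(all(is.finite(p)))
  expect_true(all(p >= 0))
  expect_equal(sum(p), 1, tolerance = 1e-6)
  # random inputs stay on the simplex
  set.seed(4)
  X <- array(rnorm(32 * 16 * 5), c(32, 16, 5))
  raw <- decooc:::.cnn_predict(m1@params, decooc:::.cnn_cfg(m1@config), X)
  expect_true(all(raw >= 0))
  expect_equal(rowSums(raw), rep(1, 5), tolerance = 1e-6)
})

test_that("too-small windows are rejected with a minimum-size message", {
  expect_error(modelConfig(2, window_size = 6), "at least 8")
})

test_that("sample prediction aggregates by averaging", {
  m <- constant_model(c(0.2, 0.8))
  x <- matrix(rnorm(32 * 16), 32, 16)
  expect_equal(unname(fractions(predictSample(m, x))), c(0.2, 0.8),
               tolerance = 1e-9)
  # duplicated tensor list predicts identically to a single copy
  X1 <- array(rnorm(32 * 16), c(32, 16, 1))
  X3 <- array(rep(X1, 3), c(32, 16, 3))
  cfg <- modelConfig(3, window_size = 16, conv_channels = c(4, 4, 4, 4),
                     dense_units = c(8, 8), seed = 9)
  mr <- buildModel(cfg)
  expect_equal(fractions(predictSample(mr, X1)),
               fractions(predictSample(mr, X3)), tolerance = 1e-12)
  # permutation of a tensor list leaves the prediction unchanged
  set.seed(6)
  Xs <- array(rnorm(32 * 16 * 4), c(32, 16, 4))
  perm <- Xs[, , c(3, 1, 4, 2)]
  expect_equal(fractions(predictSample(mr, Xs)),
               fractions(predictSample(mr, perm)), tolerance = 1e-12)
  # two constant models average to the mean composition
  ens <- new("CVEnsemble",
             models = list(constant_model(c(0.2, 0.8)),
                           constant_model(c(0.4, 0.6))),
             splitAssignment = stats::setNames(1:2, c("a", "b")),
             cellTypes = c("x", "y"))
  expect_equal(unname(fractions(predictSample(ens, x))), c(0.3, 0.7),
               tolerance = 1e-9)
})

test_that("training overfits pure single-type samples (capacity check)", {
  tpl <- tiny_templates(2, n_bins = 36, seed = 8)
  specs <- lapply(1:5, function(i) {
    f <- if (i %% 2 == 0) c(1, 0) else c(0, 1)
    new("MixtureSpec", cellTypes = names(tpl), fractions = f, seed = 1L)
  })
  samples <- lapply(1:5, function(i)
    synthesizeBulkFromPure(tpl, specs[[i]], 2e4, seed = i,
                           sample_id = paste0("p", i)))
  ds <- buildDataset(samples, c("chr1", "chr2"), n_bins = 36)
  cfg <- modelConfig(2, conv_channels = c(4, 8, 8, 8),
                     dense_units = c(16, 8), epochs_max = 200, seed = 2,
                     early_stopping_patience = 200)
  fit <- decooc:::.train_one(cfg, ds@tensors, ds@labels, ds@tensors,
                             ds@labels, seed = 1)
  train_rmse <- sqrt(min(fit$train_loss))
  expect_lt(train_rmse, 0.05)
})

test_that("training improves validation RMSE on separable mixtures", {
  tpl <- tiny_templates(2, n_bins = 36, seed = 5)
  samples <- make_mixture_samples(tpl, 36, lib_range = c(2e4, 4e4))
  ds <- buildDataset(samples, c("chr1", "chr2"), n_bins = 36)
  ids <- unique(ds@sampleId)
  tr <- subsetDataset(ds, ids[1:30])
  va <- subsetDataset(ds, ids[31:36])
  cfg <- modelConfig(2, conv_channels = c(4, 8, 8, 8),
                     dense_units = c(16, 8), epochs_max = 40, seed = 2)
  fit <- decooc:::.train_one(cfg, tr@tensors, tr@labels, va@tensors,
                             va@labels, seed = 1)
  expect_lt(fit$best_val_rmse, fit$val_rmse[1])
  # learning-rate trace is non-increasing (plateau scheduler contract)
  expect_true(all(diff(fit$lr) <= 1e-15))
})

test_that("the learning curve reports one validation metric per size", {
  tpl <- tiny_templates(2, n_bins = 36, seed = 5)
  samples <- make_mixture_samples(tpl, 12, lib_range = c(5e3, 1e4))
  ds <- buildDataset(samples, c("chr1", "chr2"), n_bins = 36)
  cfg <- modelConfig(2, conv_channels = c(2, 2, 2, 2),
                     dense_units = c(4, 4), epochs_max = 2, seed = 7)
  lc <- learningCurve(ds, sizes = c(4, 8), cfg)
  expect_equal(lc$size, c(4L, 8L))
  expect_true(all(is.finite(lc$val_rmse)))
})

test_that("fold assignment is a reproducible sample-level partition", {
  tpl <- tiny_templates(2, n_bins = 36, seed = 5)
  samples <- make_mixture_samples(tpl, 10, lib_range = c(5e3, 1e4))
  ds <- buildDataset(samples, c("chr1", "chr2"), n_bins = 36)
  cfg <- modelConfig(2, conv_channels = c(2, 2, 2, 2),
                     dense_units = c(4, 4), epochs_max = 2, seed = 7)
  e1 <- trainEnsemble(ds, cfg)
  e2 <- trainEnsemble(ds, cfg)
  expect_identical(e1@splitAssignment, e2@splitAssignment)
  # every sample in exactly one fold; folds cover 1..5
  expect_setequal(names(e1@splitAssignment), unique(ds@sampleId))
  expect_setequal(unique(e1@splitAssignment), 1:5)
  expect_length(e1@models, 5L)
  expect_error(trainEnsemble(subsetDataset(ds, unique(ds@sampleId)[1:3]),
                             cfg), "at least as many samples")
})
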