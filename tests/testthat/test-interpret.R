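# a small trained-ish model and tensors for attribution contracts
local_shap_fixture <- function(K = 3, w = 16, n = 4, seed = 44) {
  cfg <- modelConfig(K, window_size = w, conv_channels = c(4, 8, 8, 8),
                     dense_units = c(16, 8), seed = seed)
  m <- buildModel(cfg)
  set.seed(seed)
  X <- array(runif(2 * w * w * n), c(2 * w, w, n))
  list(model = m, X = X, cfg = cfg)
}

test_that("attribution maps have one map per tensor and cell type", {
  fx <- local_shap_fixture()
  shap <- shapAttribute(fx$model, fx$X[, , 1:2], fx$X, n_samples = 8)
  expect_s4_class(shap, "ShapMap")
  expect_equal(dim(shap@values), c(32L, 16L, 3L, 2L))
  expect_true(all(is.finite(shap@values)))
  expect_error(shapAttribute(fx$model, fx$X,
                             array(0, c(32, 16, 0)), n_samples = 4),
               "non-empty")
})

test_that("input equal to the single background tensor attributes ~0", {
  fx <- local_shap_fixture()
  x <- fx$X[, , 1, drop = FALSE]
  shap <- shapAttribute(fx$model, x, x, n_samples = 16)
  expect_lt(max(abs(shap@values)), 1e-12)
})

test_that("expected gradients satisfy the completeness identity", {
  fx <- local_shap_fixture()
  x <- fx$X[, , 2, drop = FALSE]
  bg <- fx$X[, , 3, drop = FALSE]
  shap <- shapAttribute(fx$model, x, bg, n_samples = 256)
  ccfg <- decooc:::.cnn_cfg(fx$model@config)
  fx_out <- decooc:::.cnn_predict(fx$model@params, ccfg, x)[1, ]
  bg_out <- decooc:::.cnn_predict(fx$model@params, ccfg, bg)[1, ]
  for (k in 1:3) {
    expect_lt(abs(sum(shap@values[, , k, 1]) - (fx_out[k] - bg_out[k])),
              5e-3)
  }
})

test_that("SHAP/contact-map correlation matches a textbook Pearson oracle", {
  # synthetic ShapMap with known window coordinates over a 40-bin genome
  set.seed(51)
  w <- 10
  vals <- array(rnorm(2 * w * w * 1 * 1), c(2 * w, w, 1, 1))
  meta <- data.frame(chrom_a = "c1", chrom_b = "c2", start_a = 5,
                     start_b = 12, sampleId = "s1")
  shap <- new("ShapMap", values = vals, cellTypes = "t1", meta = meta,
              modelIds = 1L)
  mk_oe <- function(n) {
    a <- matrix(runif(n * n, 0.5, 2), n)
    contactMatrix(a + t(a), "c")
  }
  oe <- list(c1 = mk_oe(40), c2 = mk_oe(40))
  got <- shapHicCorrelation(shap, oe)$pearson_r
  # oracle: stitch the o/e windows, correlate over positive-SHAP entries
  o1 <- contactValues(oe$c1)[6:15, 6:15]
  o2 <- contactValues(oe$c2)[13:22, 13:22]
  stitched <- rbind(o1, o2)
  pos <- vals[, , 1, 1] > 0
  sv <- vals[, , 1, 1][pos]; ov <- stitched[pos]
  n <- length(sv)
  oracle <- (mean(sv * ov) - mean(sv) * mean(ov)) /
    (sqrt(mean(sv^2) - mean(sv)^2) * sqrt(mean(ov^2) - mean(ov)^2))
  expect_equal(got, oracle, tolerance = 1e-12)
  # constant o/e map: undefined correlation reported as missing
  oe_const <- list(c1 = contactMatrix(matrix(1, 40, 40), "c",
                                      mask = rep(TRUE, 40)),
                   c2 = contactMatrix(matrix(1, 40, 40), "c",
                                      mask = rep(TRUE, 40)))
  expect_true(is.na(shapHicCorrelation(shap, oe_const)$pearson_r))
})

test_that("open fraction implements interval intersection per bin", {
  res <- 5e5
  # one 250 kb interval fully inside bin 0 -> O_f = 0.5
  iv <- data.frame(chrom = "chr1", start = 100000, end = 350000)
  tr <- openFraction(iv, res, n_bins = 4, chrom = "chr1")
  expect_equal(tr@openFraction[1], 0.5)
  # 4 kb open -> O_f = 0.008, the strict "less than" filter retains it
  iv2 <- data.frame(chrom = "chr1", start = 0, end = 4000)
  tr2 <- openFraction(iv2, res, n_bins = 2, chrom = "chr1")
  expect_equal(tr2@openFraction[1], 0.008)
  expect_false(tr2@filtered[1])
  expect_true(tr2@filtered[2])  # 0 < 0.008
  # interval spanning two bins splits proportionally
  iv3 <- data.frame(chrom = "chr1", start = 400000, end = 700000)
  tr3 <- openFraction(iv3, res, n_bins = 2, chrom = "chr1")
  expect_equal(tr3@openFraction, c(0.2, 0.4))
  # total open length is conserved
  set.seed(61)
  starts <- sort(sample.int(2e6, 20))
  iv4 <- data.frame(chrom = "chr1", start = starts,
                    end = starts + sample.int(3e4, 20))
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(iv4$start + 1, iv4$end)))
  tr4 <- openFraction(iv4, res, n_bins = 5, chrom = "chr1")
  expect_equal(sum(tr4@openFraction) * res, sum(GenomicRanges::width(gr)))
})

test_that("open fraction reads BED files", {
  f <- withr::local_tempfile(lines = "chr1\t0\t250000\tpeak1\t100\t+")
  tr <- openFraction(f, 5e5, n_bins = 2, chrom = "chr1")
  expect_equal(tr@openFraction, c(0.5, 0))
})

test_that("pairwise open fraction is the mean of the two bins", {
  tr <- new("OpenFractionTrack", openFraction = c(0.2, 0.4),
            resolution = 5e5, filtered = c(FALSE, FALSE), chrom = "c")
  expect_equal(pairwiseOpenFraction(tr, 1, 2), 0.3)
  expect_equal(pairwiseOpenFraction(tr, 1, 1), 0.2)
  expect_equal(pairwiseOpenFraction(tr, 2, 1),
               pairwiseOpenFraction(tr, 1, 2))
})

test_that("accessibility strata are tested one-sided between buckets", {
  set.seed(71)
  w <- 8
  # attribution values spread across the three strata
  vals <- array(10^runif(2 * w * w, -4, -1), c(2 * w, w, 1, 1))
  meta <- data.frame(chrom_a = "c1", chrom_b = "c1", start_a = 0,
                     start_b = 4, sampleId = "s")
  shap <- new("ShapMap", values = vals, cellTypes = "t1", meta = meta,
              modelIds = 1L)
  tr <- new("OpenFractionTrack", openFraction = runif(12, 0.01, 0.9),
            resolution = 5e5, filtered = rep(FALSE, 12), chrom = "c1")
  res <- shapAccessibilityBins(shap, list(c1 = tr), "t1")
  expect_named(res, c("groups", "tests"))
  expect_length(res$groups, 3L)
  expect_equal(nrow(res$tests), 2L)
  expect_true(all(res$tests$p_value > 0 & res$tests$p_value <= 1,
                  na.rm = TRUE))
})

test_that("high-SHAP region export follows the top-fraction tie rule", {
  w <- 5
  mk_shap <- function(vals) {
    new("ShapMap", values = vals, cellTypes = "t1",
        meta = data.frame(chrom_a = "c1", chrom_b = "c2", start_a = 0,
                          start_b = 0, sampleId = "s"), modelIds = 1L)
  }
  # all-equal attributions: exactly ceiling(0.1 * n) bins, stable order
  eq <- mk_shap(array(1, c(2 * w, w, 1, 1)))
  reg <- highShapRegions(eq, top_fraction = 0.10)
  expect_equal(nrow(reg), ceiling(0.10 * 2 * w))
  expect_equal(reg$chrom[1], "c1")
  expect_equal(reg$bin[1], 0L)
  # a single dominant entry puts its bin first
  v <- array(0.001, c(2 * w, w, 1, 1))
  v[3, 4, 1, 1] <- 5
  dom <- highShapRegions(mk_shap(v), top_fraction = 0.2)
  expect_equal(dom$bin[1], 2L)  # row 3 -> bin offset 2 on chrom a
  expect_equal(dom$chrom[1], "c1")
  # agreement with a sort-based oracle on random maps
  set.seed(81)
  rv <- array(rnorm(2 * w * w), c(2 * w, w, 1, 1))
  got <- highShapRegions(mk_shap(rv), top_fraction = 0.3)
  sv <- pmax(rv[, , 1, 1], 0)
  score_a <- pmax(apply(sv[1:w, ], 1, max), apply(sv[1:w, ], 2, max))
  score_b <- pmax(apply(sv[(w + 1):(2 * w), ], 1, max),
                  apply(sv[(w + 1):(2 * w), ], 2, max))
  all_scores <- c(score_a, score_b)
  ord <- order(-all_scores, seq_along(all_scores))
  expect_equal(got$score, all_scores[ord][seq_len(nrow(got))])
  # BED writer emits bin coordinates at the stated resolution
  f <- withr::local_tempfile()
  writeBedRegions(got, 5e5, f)
  bed <- read.table(f)
  expect_equal(bed$V3 - bed$V2, rep(5e5, nrow(got)))
})
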