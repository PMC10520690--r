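test_that("combination enumeration censuses all multi-type subsets", {
  expect_length(enumerateCombinations(4, 2), 11L)
  expect_length(enumerateCombinations(2, 2), 1L)
  expect_error(enumerateCombinations(3, 4), "empty design")
  # labelled input returns labels
  cc <- enumerateCombinations(c("a", "b", "c"), 2)
  expect_equal(cc[[1]], c("a", "b"))
  # 2^n - n - 1 subsets of size >= 2, against a brute-force bitmask oracle
  for (n in c(3, 5, 8, 14)) {
    oracle <- sum(vapply(0:(2^n - 1), function(b)
      sum(bitwAnd(b, 2^(0:(n - 1))) > 0) >= 2, logical(1)))
    expect_length(enumerateCombinations(n, 2), oracle)
    expect_equal(oracle, 2^n - n - 1)
  }
  # deterministic order: size then lexicographic
  cc4 <- enumerateCombinations(4, 2)
  expect_equal(cc4[[1]], c(1L, 2L))
  expect_equal(cc4[[11]], 1:4)
})

test_that("fraction draws are uniform ratios rounded to three decimals", {
  types <- paste0("t", 1:4)
  spec <- drawFractions(c("t2", "t4"), types, seed = 5)
  f <- fractions(spec)
  expect_equal(sum(f), 1, tolerance = 0.001)
  expect_equal(unname(f[c("t1", "t3")]), c(0, 0))
  expect_equal(f, round(f, 3))
  # determinism
  expect_equal(fractions(drawFractions(c("t2", "t4"), types, 5)), f)
  # different seeds differ
  expect_false(all(fractions(drawFractions(c("t2", "t4"), types, 6)) == f))
  # simplex slack holds over many draws
  sums <- vapply(1:200, function(s)
    sum(fractions(drawFractions(types, types, s))), numeric(1))
  expect_true(all(sums >= 0.999 & sums <= 1.001))
})

test_that("per-type allocations are exact largest-remainder counts", {
  spec <- new("MixtureSpec", cellTypes = c("a", "b"),
              fractions = c(0.25, 0.75), seed = 1L)
  expect_equal(unname(cellsPerType(spec, 1000)), c(250L, 750L))
  expect_equal(unname(contactsPerType(spec, 200)),
               c(50L, 150L))
  one <- new("MixtureSpec", cellTypes = "a", fractions = 1, seed = 1L)
  expect_equal(unname(cellsPerType(one, 7)), 7L)
  thirds <- new("MixtureSpec", cellTypes = c("a", "b", "c"),
                fractions = c(0.333, 0.333, 0.334), seed = 1L)
  expect_equal(sum(cellsPerType(thirds, 10)), 10L)
  # largest-remainder oracle: counts differ from raw shares by < 1
  set.seed(21)
  for (i in 1:50) {
    f <- runif(4); f <- round(f / sum(f), 3)
    spec_i <- new("MixtureSpec", cellTypes = paste0("t", 1:4),
                  fractions = f, seed = 1L)
    n <- sample(10:5000, 1)
    cnt <- cellsPerType(spec_i, n)
    expect_equal(sum(cnt), n)
    expect_true(all(abs(cnt - (f / sum(f)) * n) < 1))
  }
  expect_warning(cellsPerType(thirds, 2), "smaller")
})

test_that("library-size draws respect the configured range", {
  sizes <- vapply(1:50, drawLibrarySize, numeric(1), lo = 100, hi = 200)
  expect_true(all(sizes >= 100 & sizes <= 200))
  expect_equal(drawLibrarySize(3, 100, 200), drawLibrarySize(3, 100, 200))
})

test_that("single-cell synthesis is downsampling without replacement", {
  tpl <- tiny_templates(1, n_bins = 10)[[1]]
  total <- totalContacts(tpl)
  # full draw returns the entire pool
  full <- synthSingleCell(tpl, total, seed = 1)
  expect_equal(totalContacts(full), total)
  pool <- decooc:::.template_pool(tpl)
  expect_equal(sum(records(full)$count), sum(pool$count))
  # n = 0 -> empty list
  expect_equal(length(synthSingleCell(tpl, 0, seed = 1)), 0L)
  # over-draw errors
  expect_error(synthSingleCell(tpl, total + 1), "without replacement")
})

test_that("single-cell draws match the hypergeometric expectation", {
  # small known pool; mean per-pair draw counts over many seeds must sit
  # within 3 SE of the hypergeometric mean n * c_i / T
  cl <- contactList(data.frame(
    chrom_a = "chr1", bin_a = c(0L, 0L, 1L, 2L),
    chrom_b = "chr1", bin_b = c(0L, 1L, 2L, 3L),
    count = c(10L, 20L, 30L, 40L)), 1e5)
  tpl <- poolCellType(list(cl), "t")
  n <- 30L; T_ <- 100L; R <- 300L
  counts <- matrix(0, R, 4)
  for (s in seq_len(R)) {
    rec <- records(synthSingleCell(tpl, n, seed = s))
    key <- paste(rec$bin_a, rec$bin_b)
    counts[s, ] <- rec$count[match(paste(c(0, 0, 1, 2), c(0, 1, 2, 3)),
                                   key)]
  }
  counts[is.na(counts)] <- 0
  c_i <- c(10, 20, 30, 40)
  expect_mean <- n * c_i / T_
  var_i <- n * (c_i / T_) * (1 - c_i / T_) * (T_ - n) / (T_ - 1)
  se <- sqrt(var_i / R)
  expect_true(all(abs(colMeans(counts) - expect_mean) < 3 * se))
})

test_that("pooling cells aggregates counts per bin pair", {
  c1 <- contactList(data.frame(chrom_a = "chr1", bin_a = 0L,
                               chrom_b = "chr1", bin_b = 1L, count = 2L),
                    1e5)
  c2 <- contactList(data.frame(chrom_a = "chr1", bin_a = c(0L, 1L),
                               chrom_b = "chr1", bin_b = c(1L, 1L),
                               count = c(3L, 4L)), 1e5)
  tpl <- poolCellType(list(c1, c2), "t")
  v <- contactValues(tpl@matrices[["chr1"]])
  expect_equal(v[1, 2], 5)
  expect_equal(v[2, 2], 4)
  expect_equal(totalContacts(tpl), 9)
})

test_that("bulk synthesis from pure profiles keeps exact provenance", {
  tpl <- tiny_templates(2, n_bins = 20)
  spec <- new("MixtureSpec", cellTypes = names(tpl),
              fractions = c(0.3, 0.7), seed = 1L)
  bulk <- synthesizeBulkFromPure(tpl, spec, 5000, seed = 4)
  expect_equal(sum(bulk@provenance), 5000)
  expect_equal(totalContacts(bulk), 5000)
  expect_equal(unname(bulk@provenance), c(1500, 3500))
})

test_that("bulk synthesis from cells allocates and tops up cells", {
  tpl <- tiny_templates(2, n_bins = 12)
  cells <- lapply(names(tpl), function(ct)
    lapply(1:6, function(i) synthSingleCell(tpl[[ct]], 50,
                                            seed = 100 + i)))
  names(cells) <- names(tpl)
  spec <- new("MixtureSpec", cellTypes = names(tpl),
              fractions = c(0.5, 0.5), seed = 1L)
  bulk <- synthesizeBulkFromCells(cells, spec, n_sum = 10, seed = 2)
  expect_equal(sum(bulk@provenance), 10)
  expect_equal(totalContacts(bulk), 10 * 50)
  # more cells than available triggers in-silico top-up, total still exact
  bulk2 <- synthesizeBulkFromCells(cells, spec, n_sum = 16, seed = 3)
  expect_equal(sum(bulk2@provenance), 16)
  expect_equal(unname(bulk2@provenance), c(8, 8))
})

test_that("realised contact shares track the specified fractions", {
  tpl <- tiny_templates(2, n_bins = 20)
  spec <- new("MixtureSpec", cellTypes = names(tpl),
              fractions = c(0.3, 0.7), seed = 1L)
  shares <- vapply(1:50, function(s) {
    b <- synthesizeBulkFromPure(tpl, spec, 2000, seed = s)
    b@provenance[[1]] / sum(b@provenance)
  }, numeric(1))
  expect_lt(abs(mean(shares) - 0.3), 0.01)
})

test_that("template generation is deterministic and separable", {
  t1 <- makeTemplates(2, n_bins = 30, structure_seed = 9)
  t2 <- makeTemplates(2, n_bins = 30, structure_seed = 9)
  getv <- function(x) lapply(x@matrices, contactValues)
  expect_identical(lapply(t1, getv), lapply(t2, getv))
  one <- makeTemplates(1, n_bins = 20)[[1]]
  v <- contactValues(one@matrices[[1]])
  expect_true(all(v == t(v)))
  expect_true(all(diag(v) > 0))
  # four types: globally similar but not identical
  t4 <- makeTemplates(4, n_bins = 40, structure_seed = 2)
  flat <- vapply(t4, function(x)
    as.vector(contactValues(x@matrices[[1]])), numeric(40 * 40))
  cors <- cor(flat)[upper.tri(diag(4))]
  expect_true(all(cors < 1 - 1e-6))
  expect_true(all(cors > 0))
})

test_that("distance to the training design is a minimum Euclidean norm", {
  mk <- function(f, types = c("a", "b")) {
    new("MixtureSpec", cellTypes = types, fractions = f, seed = 1L)
  }
  training <- list(mk(c(1, 0)), mk(c(0, 1)))
  expect_equal(minDistanceToTraining(mk(c(0.5, 0.5)), training),
               sqrt(0.5), tolerance = 1e-12)
  expect_equal(minDistanceToTraining(mk(c(1, 0)), training), 0)
  expect_equal(minDistanceToTraining(mk(c(0.2, 0.8)),
                                     list(mk(c(0.6, 0.4)))),
               sqrt(2 * 0.4^2), tolerance = 1e-12)
})

test_that("distal-unseen selection matches a sort-based oracle", {
  set.seed(17)
  mk <- function(f) new("MixtureSpec", cellTypes = c("a", "b", "c"),
                        fractions = round(f / sum(f), 3), seed = 1L)
  training <- lapply(1:20, function(i) mk(runif(3)))
  candidates <- lapply(1:100, function(i) mk(runif(3)))
  sel <- selectDistalUnseen(candidates, training, quantile = 0.90)
  expect_length(sel, 10L)
  d <- vapply(candidates, minDistanceToTraining, numeric(1), training)
  oracle_idx <- order(-d, seq_along(d))[1:10]
  expect_equal(attr(sel, "minDistance"), d[oracle_idx])
  # quantile 0 keeps everything
  expect_length(selectDistalUnseen(candidates, training, quantile = 0),
                100L)
  # peaks mode runs and returns a subset
  sel_p <- selectDistalUnseen(candidates, training, mode = "peaks")
  expect_true(length(sel_p) >= 1 && length(sel_p) <= 100)
})
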