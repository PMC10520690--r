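test_that("contact-pair parsing maps bp to bins by floor division", {
  f <- withr::local_tempfile(lines = c(
    "chr9\t1000000\tchr9\t2500000",
    "chr9\t1000000\tchr9\t2500000",
    "chr9\t0\tchr9\t499999\t3"))
  cl <- readContactPairs(f, resolution = 5e5)
  r <- records(cl)
  expect_equal(nrow(r), 2L)
  # duplicate line aggregated to count 2
  expect_equal(r$count[r$bin_a == 2 & r$bin_b == 5], 2L)
  # both positions inside bin 0
  expect_equal(r$count[r$bin_a == 0 & r$bin_b == 0], 3L)

  # 10 random bp pairs against an independent floor-division oracle
  set.seed(7)
  pos <- matrix(sample.int(5e6, 20), ncol = 2)
  f2 <- withr::local_tempfile(lines = sprintf("c\t%d\tc\t%d",
                                              pos[, 1], pos[, 2]))
  got <- records(readContactPairs(f2, resolution = 3e5))
  oracle <- t(apply(pos, 1, function(p) sort(p %/% 3e5)))
  oracle <- oracle[order(oracle[, 1], oracle[, 2]), , drop = FALSE]
  want <- unique(data.frame(bin_a = oracle[, 1], bin_b = oracle[, 2]))
  expect_equal(got[, c("bin_a", "bin_b")],
               as.data.frame(lapply(want, as.integer)),
               ignore_attr = TRUE)
})

test_that("malformed and negative input lines are rejected by line number", {
  f <- withr::local_tempfile(lines = c("c\t1\tc\t2", "c\t1\tc"))
  expect_error(readContactPairs(f, 1), "line 2")
  f2 <- withr::local_tempfile(lines = c("c\t1\tc\t-5"))
  expect_error(readContactPairs(f2, 1), "negative")
  f3 <- withr::local_tempfile(lines = c("c\t1\tc\tx"))
  expect_error(readContactPairs(f3, 1), "line 1")
})

test_that("contact lists round-trip through the pair writer", {
  set.seed(11)
  cl <- contactList(data.frame(
    chrom_a = "chrA", bin_a = sample(0:20, 30, TRUE),
    chrom_b = "chrA", bin_b = sample(0:20, 30, TRUE),
    count = sample(1:5, 30, TRUE)), 1e5)
  f <- withr::local_tempfile()
  writeContactPairs(cl, f)
  back <- readContactPairs(f, 1e5, coords = "bin")
  expect_equal(records(back), records(cl))
})

test_that("toMatrix accumulates symmetrically and preserves totals", {
  cl <- contactList(data.frame(chrom_a = "c", bin_a = c(0L, 0L),
                               chrom_b = "c", bin_b = c(1L, 0L),
                               count = c(3L, 5L)), 1e5)
  m <- toMatrix(cl, "c", 2)
  expect_equal(contactValues(m), matrix(c(5, 3, 3, 0), 2))
  expect_error(toMatrix(cl, "c", 1), "out of bounds")

  # 100 random records against a brute-force accumulation oracle
  set.seed(3)
  rec <- data.frame(chrom_a = "c", bin_a = sample(0:9, 100, TRUE),
                    chrom_b = "c", bin_b = sample(0:9, 100, TRUE),
                    count = sample(1:4, 100, TRUE))
  cl2 <- contactList(rec, 1e5)
  got <- contactValues(toMatrix(cl2, "c", 10))
  oracle <- matrix(0, 10, 10)
  for (i in seq_len(nrow(rec))) {
    a <- rec$bin_a[i] + 1; b <- rec$bin_b[i] + 1
    oracle[a, b] <- oracle[a, b] + rec$count[i]
    if (a != b) oracle[b, a] <- oracle[b, a] + rec$count[i]
  }
  expect_equal(got, oracle)
  # total contact count recovered (off-diagonal counted once)
  expect_equal(sum(got[upper.tri(got, diag = TRUE)]), sum(rec$count))
})

test_that("KR balancing matches the closed-form 2x2 solution", {
  m <- contactMatrix(matrix(c(2, 1, 1, 2), 2), "c")
  b <- krBalance(m)
  expect_true(b@converged)
  # x solves x*(2x + x) = 1 => x = 1/sqrt(3)
  expect_equal(biasVector(b), rep(1 / sqrt(3), 2), tolerance = 1e-6)
  expect_equal(contactValues(b), matrix(c(2, 1, 1, 2) / 3, 2),
               tolerance = 1e-6)
})

test_that("KR balancing leaves a doubly stochastic matrix unchanged", {
  m <- contactMatrix(diag(4) + 0, "c", mask = rep(TRUE, 4))
  b <- krBalance(m, sparsity_cutoff = 0)
  expect_equal(biasVector(b), rep(1, 4), tolerance = 1e-8)
  expect_equal(contactValues(b), diag(4) + 0, tolerance = 1e-8)
})

test_that("KR balancing equalises row sums and preserves symmetry", {
  set.seed(5)
  for (rep in 1:5) {
    a <- matrix(runif(64, 0.1, 2), 8)
    m <- contactMatrix(a + t(a), "c")
    b <- krBalance(m, tol = 1e-10)
    v <- contactValues(b)
    rs <- rowSums(v)[binMask(b)]
    expect_true(b@converged)
    expect_lt(max(abs(rs - 1)), 1e-8)
    expect_lt(max(abs(v - t(v))), 1e-10)
  }
})

test_that("KR balancing refuses unmasked all-zero rows", {
  a <- matrix(c(0, 0, 0, 1), 2)
  m <- new("ContactMatrix", chrom = "c", resolution = 1e5, values = a,
           mask = c(TRUE, TRUE))
  expect_error(krBalance(m, sparsity_cutoff = 0), "all-zero row")
})

test_that("observed/expected divides by per-offset means", {
  # constant value per diagonal -> all ones on unmasked entries
  n <- 6
  v <- matrix(0, n, n)
  for (d in 0:(n - 1)) v[abs(row(v) - col(v)) == d] <- 10 - d
  m <- contactMatrix(v, "c")
  oe <- observedExpected(m)
  expect_true(all(contactValues(oe)[binMask(oe), binMask(oe)] == 1))

  # all-zero matrix stays all-zero
  z <- contactMatrix(matrix(0, 4, 4), "c", mask = rep(FALSE, 4))
  expect_true(all(contactValues(observedExpected(z)) == 0))

  # random 10x10 against an explicit per-offset loop oracle
  set.seed(9)
  a <- matrix(runif(100, 0.5, 3), 10)
  m2 <- contactMatrix(a + t(a), "c")
  got <- contactValues(observedExpected(m2))
  v2 <- contactValues(m2)
  oracle <- v2 * 0
  for (i in 1:10) for (j in 1:10) {
    d <- abs(i - j)
    vals <- v2[abs(row(v2) - col(v2)) == d]
    if (mean(vals) > 0) oracle[i, j] <- v2[i, j] / mean(vals)
  }
  expect_equal(got, oracle, tolerance = 1e-12)

  # scale invariance: oe(c * A) = oe(A)
  m3 <- contactMatrix(7.3 * (a + t(a)), "c")
  expect_equal(contactValues(observedExpected(m3)), got, tolerance = 1e-12)
})

test_that("dense matrix TSV round-trips bit-exactly", {
  set.seed(13)
  a <- matrix(rpois(36, 8), 6)
  m <- contactMatrix(a + t(a), "chrZ", resolution = 1e5)
  f <- withr::local_tempfile()
  writeDenseMatrix(m, f)
  back <- readDenseMatrix(f, chrom = "chrZ", resolution = 1e5)
  expect_identical(contactValues(back), contactValues(m))
})
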