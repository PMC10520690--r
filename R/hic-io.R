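#' @include AllClasses.R
NULL

#' Construct a ContactList from a data frame
#'
#' Canonicalises records so that `(chrom_a, bin_a) <= (chrom_b, bin_b)`
#' lexicographically and sums duplicate pairs.
#'
#' @param records data.frame with columns `chrom_a`, `bin_a`, `chrom_b`,
#'   `bin_b` and optionally `count` (default 1).
#' @param resolution Base pairs per bin.
#' @return A [ContactList-class].
#' @export
contactList <- function(records, resolution) {
  if (nrow(records) == 0) {
    records <- data.frame(chrom_a = character(), bin_a = integer(),
                          chrom_b = character(), bin_b = integer(),
                          count = integer())
    return(new("ContactList", records = records, resolution = resolution))
  }
  if (is.null(records$count)) records$count <- 1L
  if (any(records$bin_a < 0) || any(records$bin_b < 0))
    stop("negative bin index in contact records")
  flip <- records$chrom_a > records$chrom_b |
    (records$chrom_a == records$chrom_b & records$bin_a > records$bin_b)
  if (any(flip)) {
    tmp_c <- records$chrom_a[flip]; tmp_b <- records$bin_a[flip]
    records$chrom_a[flip] <- records$chrom_b[flip]
    records$bin_a[flip] <- records$bin_b[flip]
    records$chrom_b[flip] <- tmp_c
    records$bin_b[flip] <- tmp_b
  }
  key <- paste(records$chrom_a, records$bin_a, records$chrom_b,
               records$bin_b, sep = "\r")
  agg <- rowsum(records$count, key, reorder = FALSE)
  parts <- strsplit(rownames(agg), "\r", fixed = TRUE)
  out <- data.frame(
    chrom_a = vapply(parts, `[`, character(1), 1L),
    bin_a = as.integer(vapply(parts, `[`, character(1), 2L)),
    chrom_b = vapply(parts, `[`, character(1), 3L),
    bin_b = as.integer(vapply(parts, `[`, character(1), 4L)),
    count = as.integer(agg[, 1]))
  out <- out[order(out$chrom_a, out$bin_a, out$chrom_b, out$bin_b), ,
             drop = FALSE]
  rownames(out) <- NULL
  new("ContactList", records = out, resolution = resolution)
}

#' Read binned Hi-C contact pairs from tab-separated text
#'
#' Expects columns `chrom_a`, `pos_a`, `chrom_b`, `pos_b` and optionally
#' `count`. Coordinates are either bp positions (mapped to bins by
#' `floor(pos / resolution)`) or 0-based bin indices, stated by `coords`.
#'
#' @param path Path to a whitespace/tab-separated text file, no header.
#' @param resolution Base pairs per bin.
#' @param coords `"bp"` (default) or `"bin"`.
#' @return A [ContactList-class] with canonicalised, aggregated records.
#' @export
readContactPairs <- function(path, resolution, coords = c("bp", "bin")) {
  coords <- match.arg(coords)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(contactList(data.frame(chrom_a = character(), bin_a = integer(),
                                  chrom_b = character(), bin_b = integer()),
                       resolution))
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 4L | nf > 5L)
  if (length(bad) > 0)
    stop(sprintf("malformed contact-pair line %d: expected 4 or 5 fields, got %d",
                 bad[1], nf[bad[1]]))
  pa <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  pb <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 4L)))
  cnt <- ifelse(nf == 5L,
                suppressWarnings(as.numeric(vapply(fields, function(f)
                  if (length(f) >= 5L) f[5L] else "1", character(1)))), 1)
  bad <- which(!is.finite(pa) | !is.finite(pb) | !is.finite(cnt))
  if (length(bad) > 0)
    stop(sprintf("malformed contact-pair line %d: non-numeric field", bad[1]))
  bad <- which(pa < 0 | pb < 0)
  if (length(bad) > 0)
    stop(sprintf("negative coordinate on line %d", bad[1]))
  if (coords == "bp") {
    pa <- floor(pa / resolution)
    pb <- floor(pb / resolution)
  }
  contactList(data.frame(
    chrom_a = vapply(fields, `[`, character(1), 1L),
    bin_a = as.integer(pa),
    chrom_b = vapply(fields, `[`, character(1), 3L),
    bin_b = as.integer(pb),
    count = as.integer(cnt)), resolution)
}

#' Write a ContactList as tab-separated bin-coordinate text
#'
#' Mirrors [readContactPairs()] with `coords = "bin"` bit-exactly for
#' round-trips.
#'
#' @param x A [ContactList-class].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeContactPairs <- function(x, path) {
  utils::write.table(records(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a ContactMatrix
#'
#' @param values Symmetric non-negative square matrix.
#' @param chrom Chromosome identifier.
#' @param resolution Base pairs per bin.
#' @param mask Optional logical validity vector; by default, bins with zero
#'   marginal sum are masked.
#' @return A [ContactMatrix-class].
#' @export
contactMatrix <- function(values, chrom = "chr", resolution = 5e5,
                          mask = NULL) {
  values <- (values + t(values)) / 2  # enforce exact symmetry
  if (is.null(mask)) mask <- rowSums(values) > 0
  values[!mask, ] <- 0
  values[, !mask] <- 0
  new("ContactMatrix", chrom = as.character(chrom), resolution = resolution,
      values = values, mask = mask)
}

#' Accumulate a ContactList into a dense per-chromosome matrix
#'
#' Intra-chromosomal records of `chrom` are placed symmetrically at `(i, j)`
#' and `(j, i)`; inter-chromosomal records are ignored. Bins with zero
#' marginal sum are masked.
#'
#' @param contacts A [ContactList-class].
#' @param chrom Chromosome to extract.
#' @param n_bins Matrix dimension; must cover the largest bin index present.
#' @return A [ContactMatrix-class].
#' @export
toMatrix <- function(contacts, chrom, n_bins) {
  r <- records(contacts)
  r <- r[r$chrom_a == chrom & r$chrom_b == chrom, , drop = FALSE]
  if (nrow(r) > 0 && max(r$bin_a, r$bin_b) >= n_bins)
    stop(sprintf("bin index %d out of bounds for %d bins on %s",
                 max(r$bin_a, r$bin_b), n_bins, chrom))
  m <- matrix(0, n_bins, n_bins)
  if (nrow(r) > 0) {
    idx <- cbind(r$bin_a + 1L, r$bin_b + 1L)
    # records are duplicate-free after canonicalisation
    m[idx] <- r$count
    m[idx[, 2:1, drop = FALSE]] <- r$count
  }
  contactMatrix(m, chrom = chrom, resolution = resolution(contacts))
}

#' Read / write a dense contact matrix as TSV
#'
#' The text format has a header row and column of 0-based bin indices.
#'
#' @param path File path.
#' @param chrom,resolution Metadata attached on read.
#' @return [ContactMatrix-class] for the reader; `path` for the writer.
#' @export
readDenseMatrix <- function(path, chrom = "chr", resolution = 5e5) {
  m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1,
                                   sep = "\t", check.names = FALSE))
  dimnames(m) <- NULL
  contactMatrix(m, chrom = chrom, resolution = resolution)
}

#' @rdname readDenseMatrix
#' @param x A [ContactMatrix-class] to write.
#' @export
writeDenseMatrix <- function(x, path) {
  m <- contactValues(x)
  dimnames(m) <- list(seq_len(nrow(m)) - 1L, seq_len(ncol(m)) - 1L)
  utils::write.table(m, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Knight-Ruiz matrix balancing
#'
#' Balances a symmetric non-negative contact matrix with the Knight-Ruiz
#' inner-outer Newton iteration so that `diag(bias) %*% A %*% diag(bias)`
#' has unmasked row sums equal to 1. Sparse rows (fewer than
#' `sparsity_cutoff` nonzero entries among unmasked columns) are masked
#' before balancing, mirroring the common practice of dropping low-coverage
#' bins.
#'
#' @param matrix A [ContactMatrix-class] (symmetric; masked bins excluded).
#' @param tol Convergence tolerance on the residual `1 - x * (A x)`
#'   (infinity norm of row-sum deviation bounded by `tol`).
#' @param max_iter Maximum number of matrix-vector products.
#' @param sparsity_cutoff Minimum fraction of nonzero entries for a row to
#'   enter balancing (default 0.1).
#' @return A [BalancedMatrix-class]; `converged = FALSE` with the partial
#'   result if `max_iter` is exhausted.
#' @export
krBalance <- function(matrix, tol = 1e-6, max_iter = 1000,
                      sparsity_cutoff = 0.1) {
  mask <- binMask(matrix)
  A_full <- contactValues(matrix)
  # sparsity filter on unmasked rows
  if (any(mask)) {
    nz_frac <- rowSums(A_full[, mask, drop = FALSE] > 0) / sum(mask)
    mask <- mask & nz_frac >= sparsity_cutoff
  }
  n <- sum(mask)
  bias <- rep(NA_real_, nBins(matrix))
  balanced <- A_full * 0
  if (n == 0) {
    cm <- contactMatrix(balanced, chrom = chrom(matrix),
                        resolution = resolution(matrix), mask = mask)
    return(new("BalancedMatrix", matrix = cm, bias = bias,
               converged = TRUE, iterations = 0L))
  }
  A <- A_full[mask, mask, drop = FALSE]
  if (any(rowSums(A) == 0))
    stop("unmasked all-zero row encountered; mask it or raise sparsity_cutoff")
  res <- .kr_core(A, tol = tol, max_iter = max_iter)
  x <- res$x
  bias[mask] <- x
  B <- A * tcrossprod(x)
  balanced[mask, mask] <- B
  balanced <- (balanced + t(balanced)) / 2
  cm <- contactMatrix(balanced, chrom = chrom(matrix),
                      resolution = resolution(matrix), mask = mask)
  new("BalancedMatrix", matrix = cm, bias = bias,
      converged = res$converged, iterations = as.integer(res$iterations))
}

# Knight-Ruiz inner-outer Newton iteration on a strictly balanceable
# symmetric matrix; returns x with diag(x) A diag(x) row sums ~ 1.
.kr_core <- function(A, tol = 1e-6, max_iter = 1000, delta = 0.1,
                     Delta = 3) {
  n <- nrow(A)
  e <- rep(1, n)
  x <- e
  g <- 0.9; etamax <- 0.1; eta <- etamax
  stop_tol <- tol * 0.5
  rt <- tol^2
  v <- x * as.vector(A %*% x)
  rk <- 1 - v
  rho_km1 <- sum(rk * rk)
  rout <- rho_km1; rold <- rout
  mvp <- 1L
  while (rout > rt && mvp < max_iter) {
    k <- 0L
    y <- e
    innertol <- max(eta^2 * rout, rt)
    Z <- p <- NULL
    rho_km2 <- rho_km1
    while (rho_km1 > innertol && mvp < max_iter) {
      k <- k + 1L
      if (k == 1L) {
        Z <- rk / v
        p <- Z
        rho_km1 <- sum(rk * Z)
      } else {
        beta <- rho_km1 / rho_km2
        p <- Z + beta * p
      }
      w <- x * as.vector(A %*% (x * p)) + v * p
      mvp <- mvp + 1L
      alpha <- rho_km1 / sum(p * w)
      ap <- alpha * p
      ynew <- y + ap
      if (min(ynew) <= delta) {
        ind <- which(ap < 0)
        gamma <- min((delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      if (max(ynew) >= Delta) {
        ind <- which(ynew > Delta)
        gamma <- min((Delta - y[ind]) / ap[ind])
        y <- y + gamma * ap
        break
      }
      y <- ynew
      rk <- rk - alpha * w
      rho_km2 <- rho_km1
      Z <- rk / v
      rho_km1 <- sum(rk * Z)
    }
    x <- x * y
    v <- x * as.vector(A %*% x)
    mvp <- mvp + 1L
    rk <- 1 - v
    rho_km1 <- sum(rk * rk)
    rout <- rho_km1
    rat <- rout / rold
    rold <- rout
    eta_o <- eta
    eta <- g * rat
    if (g * eta_o^2 > 0.1) eta <- max(eta, g * eta_o^2)
    eta <- max(min(eta, etamax), stop_tol / sqrt(rout))
  }
  list(x = x, converged = rout <= rt, iterations = mvp)
}

#' Observed/expected distance normalisation
#'
#' Divides each entry by the mean value at its diagonal offset, the mean
#' being taken over pairs of unmasked bins only. Offsets whose mean is zero
#' yield zeros. Removes the distance-decay backbone so compartment-scale
#' structure stands out.
#'
#' @param matrix A [ContactMatrix-class].
#' @return A [ContactMatrix-class] of observed/expected ratios.
#' @export
observedExpected <- function(matrix) {
  v <- contactValues(matrix)
  mask <- binMask(matrix)
  n <- nrow(v)
  out <- v * 0
  if (any(mask)) {
    idx <- which(mask)
    off <- abs(outer(idx, idx, "-"))
    sub <- v[idx, idx, drop = FALSE]
    # per-offset means over unmasked pairs
    means <- vapply(0:(n - 1), function(d) {
      sel <- off == d
      if (any(sel)) mean(sub[sel]) else 0
    }, numeric(1))
    full_off <- abs(outer(seq_len(n), seq_len(n), "-"))
    denom <- matrix(means[full_off + 1L], n, n)
    ok <- denom > 0 & outer(mask, mask, "&")
    out[ok] <- v[ok] / denom[ok]
  }
  contactMatrix(out, chrom = chrom(matrix), resolution = resolution(matrix),
                mask = mask)
}
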