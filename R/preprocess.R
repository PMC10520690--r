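#' @include AllClasses.R hic-io.R
NULL

#' Scale a balanced matrix into probability-like rows
#'
#' Divides every unmasked row of the balanced matrix by its row sum
#' (`V_scaled[i, j] = V[i, j] / S_i` with `S_i` the sum of row `i`), giving
#' each row the form of a contact probability distribution. Rows of masked
#' bins (zero sum) stay zero.
#'
#' @param balanced A [BalancedMatrix-class] (a plain [ContactMatrix-class]
#'   is also accepted).
#' @return A [RowScaledMatrix-class].
#' @export
scaleRows <- function(balanced) {
  v <- contactValues(balanced)
  mask <- binMask(balanced)
  ch <- if (is(balanced, "BalancedMatrix")) chrom(balanced@matrix)
        else chrom(balanced)
  res <- if (is(balanced, "BalancedMatrix")) resolution(balanced@matrix)
         else resolution(balanced)
  s <- rowSums(v)
  keep <- mask & s > 0
  v[keep, ] <- v[keep, , drop = FALSE] / s[keep]
  v[!keep, ] <- 0
  new("RowScaledMatrix", values = v, mask = keep, chrom = ch,
      resolution = res)
}

#' Extract square windows along the matrix diagonal
#'
#' Slides a `size x size` window along the diagonal at offsets
#' `0, step, 2*step, ...` up to `n_bins - size`, yielding
#' `floor((n_bins - size) / step) + 1` submatrices.
#'
#' @param matrix A [RowScaledMatrix-class] (or any object with
#'   `contactValues`).
#' @param size Window side length in bins (default 30).
#' @param step Diagonal step in bins (default 20).
#' @param reject_masked Reject windows in which more than this fraction of
#'   bins is masked (default `NULL`: keep all windows, masked bins as
#'   zeros).
#' @return List of `size x size` matrices; each carries attributes `offset`
#'   (0-based diagonal bin offset) and `chrom`.
#' @export
extractWindows <- function(matrix, size = 30, step = 20,
                           reject_masked = NULL) {
  v <- contactValues(matrix)
  n <- nrow(v)
  if (n < size)
    stop(sprintf("chromosome %s has %d bins, fewer than the window size %d",
                 chrom(matrix), n, size))
  offsets <- as.integer(seq.int(0L, n - size, by = step))
  mask <- binMask(matrix)
  out <- list()
  for (o in offsets) {
    span <- (o + 1L):(o + size)
    if (!is.null(reject_masked) &&
        mean(!mask[span]) > reject_masked) next
    w <- v[span, span, drop = FALSE]
    attr(w, "offset") <- as.integer(o)
    attr(w, "chrom") <- chrom(matrix)
    out[[length(out) + 1L]] <- w
  }
  out
}

#' Stitch window lists from two chromosomes into pair tensors
#'
#' Pairs windows by index (the i-th window of chromosome A with the i-th of
#' chromosome B, truncating to the shorter list) and stacks each pair along
#' the row axis: rows `1..w` hold the window from the first chromosome,
#' rows `w+1..2w` the window from the second.
#'
#' @param windows_a,windows_b Window lists from [extractWindows()].
#' @return List of `2w x w` matrices with attributes `chrom_a`, `chrom_b`,
#'   `start_a`, `start_b`.
#' @export
stitchPairs <- function(windows_a, windows_b) {
  if (length(windows_a) == 0 || length(windows_b) == 0)
    stop("cannot stitch: empty window list")
  n <- min(length(windows_a), length(windows_b))
  lapply(seq_len(n), function(i) {
    t <- rbind(windows_a[[i]], windows_b[[i]])
    attr(t, "chrom_a") <- attr(windows_a[[i]], "chrom")
    attr(t, "chrom_b") <- attr(windows_b[[i]], "chrom")
    attr(t, "start_a") <- attr(windows_a[[i]], "offset")
    attr(t, "start_b") <- attr(windows_b[[i]], "offset")
    t
  })
}

#' Preprocess one bulk sample into window-pair tensors
#'
#' Runs the full per-sample pipeline: bin the contacts of the two
#' chromosomes into dense matrices, Knight-Ruiz balance, row-scale, extract
#' diagonal windows, and stitch the two chromosomes' windows into pair
#' tensors.
#'
#' @param sample A [BulkSample-class] (or a [ContactList-class]).
#' @param chrom_pair Character vector of the two chromosomes to use.
#' @param n_bins Bins per chromosome.
#' @param window Window size in bins (default 30).
#' @param step Diagonal step in bins (default 20).
#' @param kr_tol,kr_max_iter Balancing controls passed to [krBalance()].
#' @return List of stitched `2w x w` tensors (see [stitchPairs()]).
#' @export
sampleTensors <- function(sample, chrom_pair, n_bins, window = 30,
                          step = 20, kr_tol = 1e-6, kr_max_iter = 1000) {
  stopifnot(length(chrom_pair) == 2)
  contacts <- if (is(sample, "BulkSample")) sample@contacts else sample
  wins <- lapply(chrom_pair, function(ch) {
    m <- toMatrix(contacts, ch, n_bins)
    b <- krBalance(m, tol = kr_tol, max_iter = kr_max_iter)
    extractWindows(scaleRows(b), size = window, step = step)
  })
  stitchPairs(wins[[1]], wins[[2]])
}

#' Build a labelled tensor dataset from bulk samples
#'
#' Applies [sampleTensors()] to every sample and labels each resulting
#' tensor with the sample's full ground-truth fraction vector. Order is
#' deterministic: samples in input order, windows in diagonal order.
#'
#' @param samples List of [BulkSample-class].
#' @param chrom_pair Character vector of the two chromosomes to use.
#' @param n_bins Bins per chromosome.
#' @param window,step Window geometry in bins.
#' @param kr_tol,kr_max_iter Balancing controls.
#' @param verbose Log progress.
#' @return A [DeconvDataset-class].
#' @export
buildDataset <- function(samples, chrom_pair, n_bins, window = 30,
                         step = 20, kr_tol = 1e-6, kr_max_iter = 1000,
                         verbose = FALSE) {
  stopifnot(length(samples) > 0)
  ct <- cellTypes(samples[[1]]@spec)
  tensors <- list()
  labels <- list()
  ids <- character()
  meta <- list()
  for (s in samples) {
    tl <- sampleTensors(s, chrom_pair, n_bins, window = window,
                        step = step, kr_tol = kr_tol,
                        kr_max_iter = kr_max_iter)
    for (t in tl) {
      tensors[[length(tensors) + 1L]] <- t
      labels[[length(labels) + 1L]] <- unname(fractions(s@spec))
      ids <- c(ids, s@sampleId)
      meta[[length(meta) + 1L]] <- data.frame(
        chrom_a = attr(t, "chrom_a"), chrom_b = attr(t, "chrom_b"),
        start_a = attr(t, "start_a"), start_b = attr(t, "start_b"))
    }
    if (verbose) .log_stage("preprocess", s@sampleId, ":", length(tl),
                            "tensors")
  }
  arr <- array(unlist(tensors), dim = c(nrow(tensors[[1]]),
                                        ncol(tensors[[1]]),
                                        length(tensors)))
  new("DeconvDataset", tensors = arr,
      labels = do.call(rbind, labels), sampleId = ids, cellTypes = ct,
      meta = do.call(rbind, meta))
}

#' Subset a dataset by tensor index or sample id
#'
#' @param dataset A [DeconvDataset-class].
#' @param idx Integer tensor indices, or a character vector of sample ids.
#' @return A [DeconvDataset-class].
#' @export
subsetDataset <- function(dataset, idx) {
  if (is.character(idx)) idx <- which(dataset@sampleId %in% idx)
  new("DeconvDataset",
      tensors = dataset@tensors[, , idx, drop = FALSE],
      labels = dataset@labels[idx, , drop = FALSE],
      sampleId = dataset@sampleId[idx],
      cellTypes = dataset@cellTypes,
      meta = dataset@meta[idx, , drop = FALSE])
}
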