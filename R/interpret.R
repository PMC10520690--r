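#' @include model.R
NULL

#' Expected-gradients SHAP attribution
#'
#' Attributes each model output (cell-type fraction) to the entries of the
#' input window-pair tensors by expected gradients, the sampling
#' approximation of integrated Shapley values used by gradient-based SHAP
#' explainers: for input `x`, background draw `b` and path position
#' `alpha`, the attribution of entry `i` is the average of
#' `(x_i - b_i) * d f_k / d x_i` evaluated at `b + alpha (x - b)`.
#' Backgrounds are drawn uniformly from the background set and `alpha` is
#' stratified over `(0, 1)` (midpoint rule), which makes the completeness
#' identity `sum(attributions) = f_k(x) - mean f_k(background)` accurate
#' already at moderate sample counts. Per-model attributions are averaged
#' over the fold models to give the final map.
#'
#' @param object A [CVEnsemble-class] or a single [DeconvModel-class].
#' @param tensors Tensors to explain ([DeconvDataset-class], array or
#'   list).
#' @param background Background tensors, typically the model's training
#'   tensors. Must be non-empty; capped at `background_cap` by random
#'   subsampling.
#' @param n_samples Path samples per explanation (default 64).
#' @param background_cap Maximum background tensors used (default 100).
#' @param seed Integer seed for background pairing.
#' @param per_model Return one [ShapMap-class] per fold model instead of
#'   their average.
#' @return A [ShapMap-class] (or a list of them when `per_model = TRUE`).
#' @export
shapAttribute <- function(object, tensors, background, n_samples = 64,
                          background_cap = 100, seed = 1,
                          per_model = FALSE) {
  models <- if (is(object, "CVEnsemble")) object@models else list(object)
  ct <- if (is(object, "CVEnsemble")) cellTypes(object) else
    paste0("type", seq_len(object@config$nCellTypes))
  X <- .dataset_tensors(tensors)
  B <- .dataset_tensors(background)
  if (dim(B)[3] == 0) stop("background must be non-empty")
  if (dim(B)[3] > background_cap) {
    keep <- .with_substream(seed, "background_cap",
                            sample.int(dim(B)[3], background_cap))
    B <- B[, , keep, drop = FALSE]
  }
  nb <- dim(B)[3]
  nt <- dim(X)[3]
  K <- length(ct)
  meta <- if (is(tensors, "DeconvDataset")) {
    cbind(tensors@meta, sampleId = tensors@sampleId)
  } else {
    data.frame(chrom_a = NA, chrom_b = NA, start_a = NA, start_b = NA,
               sampleId = rep(NA_character_, nt))
  }
  alphas <- (seq_len(n_samples) - 0.5) / n_samples
  per <- lapply(seq_along(models), function(mi) {
    m <- models[[mi]]
    cfg <- .cnn_cfg(m@config)
    vals <- array(0, dim = c(dim(X)[1], dim(X)[2], K, nt))
    for (ti in seq_len(nt)) {
      x <- X[, , ti]
      bsel <- .with_substream(seed, paste0("bg_", mi, "_", ti),
                              sample.int(nb, n_samples, replace = TRUE))
      # path points b + alpha (x - b), batched per tensor
      P <- array(0, dim = c(dim(X)[1], dim(X)[2], n_samples))
      D <- array(0, dim = c(dim(X)[1], dim(X)[2], n_samples))
      for (j in seq_len(n_samples)) {
        b <- B[, , bsel[j]]
        D[, , j] <- x - b
        P[, , j] <- b + alphas[j] * (x - b)
      }
      for (k in seq_len(K)) {
        g <- .cnn_input_grad(m@params, cfg, P, k)
        vals[, , k, ti] <- apply(g * D, c(1, 2), mean)
      }
    }
    new("ShapMap", values = vals, cellTypes = ct, meta = meta,
        modelIds = as.integer(mi))
  })
  if (per_model) return(per)
  avg <- Reduce(`+`, lapply(per, function(s) s@values)) / length(per)
  new("ShapMap", values = avg, cellTypes = ct, meta = meta,
      modelIds = seq_along(models))
}

# stitched observed/expected tensor matching the window coordinates of one
# explained tensor
.stitch_oe <- function(oe_list, meta_row, w) {
  get_win <- function(ch, start) {
    m <- contactValues(oe_list[[as.character(ch)]])
    span <- (start + 1):(start + w)
    m[span, span, drop = FALSE]
  }
  rbind(get_win(meta_row$chrom_a, meta_row$start_a),
        get_win(meta_row$chrom_b, meta_row$start_b))
}

#' Correlate SHAP attributions with observed/expected Hi-C
#'
#' Pearson correlation between the observed/expected contact values and
#' the SHAP attributions, computed over positive-SHAP positions per cell
#' type present in the sample, then averaged across cell types within each
#' tensor. A weak correlation indicates that the network does not simply
#' read contact intensity.
#'
#' @param shap A [ShapMap-class] with window coordinates in its meta.
#' @param oe_list Named list (by chromosome) of observed/expected
#'   [ContactMatrix-class] (see [observedExpected()]).
#' @param present Optional list (one per tensor) of character vectors of
#'   cell types present in the tensor's sample; default: all types.
#' @return data.frame with per-tensor mean Pearson `r` (NA when no
#'   positive-SHAP positions exist or the o/e values are constant).
#' @export
shapHicCorrelation <- function(shap, oe_list, present = NULL) {
  d <- dim(shap@values)
  w <- d[2]
  out <- vapply(seq_len(d[4]), function(ti) {
    oe <- .stitch_oe(oe_list, shap@meta[ti, ], w)
    types <- if (is.null(present)) cellTypes(shap) else present[[ti]]
    rs <- vapply(types, function(ctype) {
      k <- match(ctype, cellTypes(shap))
      sv <- shap@values[, , k, ti]
      pos <- sv > 0
      if (sum(pos) < 3) return(NA_real_)
      o <- oe[pos]
      if (stats::sd(o) == 0 || stats::sd(sv[pos]) == 0) return(NA_real_)
      stats::cor(o, sv[pos])
    }, numeric(1))
    mean(rs, na.rm = TRUE)
  }, numeric(1))
  data.frame(tensor = seq_len(d[4]), sampleId = shap@meta$sampleId,
             pearson_r = out)
}

#' Per-bin open-chromatin fraction
#'
#' Computes the open fraction `O_f = sum(L_r) / bin_length` of each
#' genomic bin, where `L_r` are the lengths of the accessible-chromatin
#' intervals intersected with the bin. Bins with `O_f < 0.008` are flagged
#' as filtered; the boundary value itself is retained.
#'
#' @param intervals Open-chromatin intervals: a `GRanges`, a data.frame
#'   with columns `chrom`, `start`, `end` (0-based half-open, BED
#'   convention), or a path to a BED file.
#' @param resolution Bin length in bp.
#' @param n_bins Number of bins on the chromosome.
#' @param chrom Chromosome to extract.
#' @return An [OpenFractionTrack-class].
#' @export
openFraction <- function(intervals, resolution, n_bins, chrom = "chr") {
  if (is.character(intervals))
    intervals <- rtracklayer::import(intervals, format = "BED")
  if (is.data.frame(intervals))
    intervals <- GenomicRanges::GRanges(
      intervals$chrom,
      IRanges::IRanges(start = intervals$start + 1L, end = intervals$end))
  intervals <- intervals[as.character(
    GenomicRanges::seqnames(intervals)) == chrom]
  intervals <- GenomicRanges::reduce(intervals)
  bins <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = (seq_len(n_bins) - 1L) * resolution + 1L,
                            width = resolution))
  hits <- GenomicRanges::findOverlaps(bins, intervals)
  ov <- GenomicRanges::pintersect(
    bins[S4Vectors::queryHits(hits)], intervals[S4Vectors::subjectHits(hits)])
  open_len <- numeric(n_bins)
  if (length(hits) > 0) {
    agg <- rowsum(GenomicRanges::width(ov), S4Vectors::queryHits(hits))
    open_len[as.integer(rownames(agg))] <- agg[, 1]
  }
  of <- pmin(1, open_len / resolution)
  new("OpenFractionTrack", openFraction = of, resolution = resolution,
      filtered = of < 0.008, chrom = chrom)
}

#' Pairwise open fraction of a matrix element
#'
#' The open fraction of an off-diagonal element `(i, j)` of an attribution
#' or contact matrix is the mean of the two bins' open fractions,
#' `O_f(i, j) = (O_f(i) + O_f(j)) / 2`.
#'
#' @param track An [OpenFractionTrack-class].
#' @param i,j 1-based bin indices.
#' @return Numeric in `[0, 1]`.
#' @export
pairwiseOpenFraction <- function(track, i, j) {
  (track@openFraction[i] + track@openFraction[j]) / 2
}

#' Chromatin accessibility across SHAP-value strata
#'
#' Buckets SHAP entries by attribution value (default strata
#' `(1e-4, 1e-3]`, `(1e-3, 1e-2]`, `(1e-2, 1e-1]`), pairs each entry with
#' the pairwise open fraction of its two bins (entries touching a filtered
#' bin are dropped), and tests whether accessibility increases with the
#' attribution stratum using one-sided Mann-Whitney U tests between
#' consecutive strata.
#'
#' @param shap A [ShapMap-class].
#' @param tracks Named list (by chromosome) of [OpenFractionTrack-class].
#' @param cell_type Cell type whose attribution maps to analyse.
#' @param boundaries List of `(lo, hi]` stratum boundaries.
#' @return List with `groups` (named list of open-fraction vectors per
#'   stratum) and `tests` (data.frame of one-sided Mann-Whitney p-values,
#'   alternative: higher stratum has greater accessibility).
#' @export
shapAccessibilityBins <- function(shap, tracks, cell_type,
                                  boundaries = list(c(1e-4, 1e-3),
                                                    c(1e-3, 1e-2),
                                                    c(1e-2, 1e-1))) {
  k <- match(cell_type, cellTypes(shap))
  if (is.na(k)) stop("unknown cell type: ", cell_type)
  d <- dim(shap@values)
  w <- d[2]
  vals <- list()
  ofs <- list()
  for (ti in seq_len(d[4])) {
    mrow <- shap@meta[ti, ]
    sv <- shap@values[, , k, ti]
    for (block in 1:2) {
      ch <- as.character(if (block == 1) mrow$chrom_a else mrow$chrom_b)
      start <- if (block == 1) mrow$start_a else mrow$start_b
      track <- tracks[[ch]]
      if (is.null(track)) next
      rows <- if (block == 1) 1:w else (w + 1):(2 * w)
      rc <- expand.grid(r = seq_len(w), c = seq_len(w))
      bi <- start + rc$r
      bj <- start + rc$c
      ok <- !track@filtered[bi] & !track@filtered[bj]
      vals[[length(vals) + 1L]] <- sv[rows, ][cbind(rc$r, rc$c)][ok]
      ofs[[length(ofs) + 1L]] <-
        pairwiseOpenFraction(track, bi[ok], bj[ok])
    }
  }
  v <- unlist(vals)
  o <- unlist(ofs)
  groups <- lapply(boundaries, function(b) o[v > b[1] & v <= b[2]])
  names(groups) <- vapply(boundaries, function(b)
    sprintf("(%g, %g]", b[1], b[2]), character(1))
  tests <- NULL
  if (length(groups) >= 2) {
    cmp <- lapply(seq_len(length(groups) - 1L), function(i) {
      hi <- groups[[i + 1]]; lo <- groups[[i]]
      p <- if (length(hi) > 0 && length(lo) > 0)
        stats::wilcox.test(hi, lo, alternative = "greater",
                           exact = FALSE)$p.value else NA_real_
      data.frame(higher = names(groups)[i + 1], lower = names(groups)[i],
                 n_higher = length(hi), n_lower = length(lo), p_value = p)
    })
    tests <- do.call(rbind, cmp)
  }
  list(groups = groups, tests = tests)
}

#' Export high-SHAP bins as BED records
#'
#' Aggregates window-level attributions to bin level -- a bin covered by
#' several overlapping windows takes the maximum positive attribution of
#' any matrix entry in its row or column -- and keeps, per cell type and
#' chromosome, the bins in the top `top_fraction` (ties broken by bin
#' order, exactly `ceiling(top_fraction * n)` bins).
#'
#' @param shap A [ShapMap-class].
#' @param top_fraction Fraction of covered bins to keep (default 0.10).
#' @return data.frame in BED-like form: `chrom`, `start`, `end`,
#'   `cell_type`, `score`, ordered by decreasing score within cell type.
#' @export
highShapRegions <- function(shap, top_fraction = 0.10) {
  d <- dim(shap@values)
  w <- d[2]
  res <- list()
  for (k in seq_along(cellTypes(shap))) {
    # bin score = max positive attribution over covering entries/windows
    scores <- list()
    for (ti in seq_len(d[4])) {
      mrow <- shap@meta[ti, ]
      sv <- pmax(shap@values[, , k, ti], 0)
      for (block in 1:2) {
        ch <- as.character(if (block == 1) mrow$chrom_a else mrow$chrom_b)
        start <- if (block == 1) mrow$start_a else mrow$start_b
        rows <- if (block == 1) 1:w else (w + 1):(2 * w)
        blk <- sv[rows, , drop = FALSE]
        per_bin <- pmax(apply(blk, 1, max), apply(blk, 2, max))
        for (r in seq_len(w)) {
          key <- paste0(ch, ":", start + r - 1L)
          scores[[key]] <- max(scores[[key]] %||% -Inf, per_bin[r])
        }
      }
    }
    bins <- names(scores)
    sc <- unlist(scores, use.names = FALSE)
    n_top <- ceiling(top_fraction * length(bins))
    ord <- order(-sc, seq_along(sc))
    sel <- ord[seq_len(n_top)]
    parts <- strsplit(bins[sel], ":", fixed = TRUE)
    res[[k]] <- data.frame(
      chrom = vapply(parts, `[`, character(1), 1L),
      bin = as.integer(vapply(parts, `[`, character(1), 2L)),
      cell_type = cellTypes(shap)[k], score = sc[sel])
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write high-SHAP regions as a BED file
#'
#' @param regions Output of [highShapRegions()].
#' @param resolution Bin length in bp.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBedRegions <- function(regions, resolution, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$bin * resolution,
                    end = (regions$bin + 1) * resolution,
                    name = regions$cell_type,
                    score = signif(regions$score, 6))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
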