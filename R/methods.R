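#' @include AllClasses.R
NULL

## Accessors ------------------------------------------------------------------

#' @rdname accessors
#' @aliases chrom,ContactMatrix-method
setMethod("chrom", "ContactMatrix", function(x, ...) x@chrom)
#' @rdname accessors
setMethod("chrom", "RowScaledMatrix", function(x, ...) x@chrom)

#' @rdname accessors
setMethod("resolution", "ContactList", function(x, ...) x@resolution)
#' @rdname accessors
setMethod("resolution", "ContactMatrix", function(x, ...) x@resolution)
#' @rdname accessors
setMethod("resolution", "RowScaledMatrix", function(x, ...) x@resolution)
#' @rdname accessors
setMethod("resolution", "OpenFractionTrack", function(x, ...) x@resolution)

#' @rdname accessors
setMethod("contactValues", "ContactMatrix", function(x, ...) x@values)
#' @rdname accessors
setMethod("contactValues", "BalancedMatrix", function(x, ...)
  x@matrix@values)
#' @rdname accessors
setMethod("contactValues", "RowScaledMatrix", function(x, ...) x@values)

#' @rdname accessors
setMethod("binMask", "ContactMatrix", function(x, ...) x@mask)
#' @rdname accessors
setMethod("binMask", "BalancedMatrix", function(x, ...) x@matrix@mask)
#' @rdname accessors
setMethod("binMask", "RowScaledMatrix", function(x, ...) x@mask)

#' @rdname accessors
setMethod("nBins", "ContactMatrix", function(x, ...) nrow(x@values))
#' @rdname accessors
setMethod("nBins", "BalancedMatrix", function(x, ...) nrow(x@matrix@values))
#' @rdname accessors
setMethod("nBins", "RowScaledMatrix", function(x, ...) nrow(x@values))
#' @rdname accessors
setMethod("nBins", "OpenFractionTrack", function(x, ...)
  length(x@openFraction))

#' @rdname accessors
setMethod("records", "ContactList", function(x, ...) x@records)
#' @rdname accessors
setMethod("records", "BulkSample", function(x, ...) x@contacts@records)

#' @rdname accessors
setMethod("biasVector", "BalancedMatrix", function(x, ...) x@bias)

#' @rdname accessors
setMethod("fractions", "MixtureSpec", function(x, ...)
  stats::setNames(x@fractions, x@cellTypes))
#' @rdname accessors
setMethod("fractions", "BulkSample", function(x, ...) fractions(x@spec))

#' @rdname accessors
setMethod("cellTypes", "MixtureSpec", function(x, ...) x@cellTypes)
#' @rdname accessors
setMethod("cellTypes", "CellTypeTemplate", function(x, ...) x@cellType)
#' @rdname accessors
setMethod("cellTypes", "DeconvDataset", function(x, ...) x@cellTypes)
#' @rdname accessors
setMethod("cellTypes", "CVEnsemble", function(x, ...) x@cellTypes)
#' @rdname accessors
setMethod("cellTypes", "ShapMap", function(x, ...) x@cellTypes)

#' @rdname accessors
setMethod("totalContacts", "ContactList", function(x, ...)
  sum(x@records$count))
#' @rdname accessors
setMethod("totalContacts", "CellTypeTemplate", function(x, ...)
  x@totalContacts)
#' @rdname accessors
setMethod("totalContacts", "BulkSample", function(x, ...)
  sum(x@contacts@records$count))

#' @rdname accessors
setMethod("length", "ContactList", function(x) nrow(x@records))
#' @rdname accessors
setMethod("length", "DeconvDataset", function(x) dim(x@tensors)[3])

## show -----------------------------------------------------------------------

setMethod("show", "ContactList", function(object) {
  cat("ContactList:", nrow(object@records), "bin pairs,",
      sum(object@records$count), "contacts @",
      format(object@resolution, big.mark = ","), "bp\n")
})

setMethod("show", "ContactMatrix", function(object) {
  cat("ContactMatrix", object@chrom, ":", nBins(object), "x", nBins(object),
      "bins @", format(object@resolution, big.mark = ","), "bp;",
      sum(!object@mask), "masked bins\n")
})

setMethod("show", "BalancedMatrix", function(object) {
  cat("BalancedMatrix", object@matrix@chrom, ":", nBins(object), "bins;",
      if (object@converged) "converged" else "NOT converged", "after",
      object@iterations, "matrix-vector products\n")
})

setMethod("show", "MixtureSpec", function(object) {
  cat("MixtureSpec (K =", length(object@cellTypes), "):",
      paste(sprintf("%s=%.3f", object@cellTypes, object@fractions),
            collapse = ", "), "\n")
})

setMethod("show", "CellTypeTemplate", function(object) {
  cat("CellTypeTemplate", object@cellType, ":", length(object@matrices),
      "chromosome(s),", format(object@totalContacts, big.mark = ","),
      "contacts\n")
})

setMethod("show", "BulkSample", function(object) {
  cat("BulkSample", object@sampleId, ":", totalContacts(object),
      "contacts\n  ")
  show(object@spec)
})

setMethod("show", "DeconvDataset", function(object) {
  d <- dim(object@tensors)
  cat("DeconvDataset:", d[3], "tensors of", d[1], "x", d[2], "from",
      length(unique(object@sampleId)), "samples; K =",
      length(object@cellTypes), "\n")
})

setMethod("show", "DeconvModel", function(object) {
  cat("DeconvModel: window", object@config$windowSize, "bins, K =",
      object@config$nCellTypes, ", conv channels",
      paste(object@config$convChannels, collapse = "-"),
      if (isTRUE(object@frozenConv)) "(conv frozen)" else "", "\n")
  if (length(object@history))
    cat("  trained", length(object@history$train_loss), "epochs; best val RMSE",
        signif(object@history$best_val_rmse, 4), "\n")
})

setMethod("show", "CVEnsemble", function(object) {
  cat("CVEnsemble:", length(object@models), "fold models, K =",
      length(object@cellTypes), "(",
      paste(object@cellTypes, collapse = ", "), ")\n")
})

setMethod("show", "ShapMap", function(object) {
  d <- dim(object@values)
  cat("ShapMap:", d[4], "tensors x", d[3], "cell types, maps", d[1], "x",
      d[2], "; mean over models", paste(object@modelIds, collapse = ","),
      "\n")
})

setMethod("show", "OpenFractionTrack", function(object) {
  cat("OpenFractionTrack", object@chrom, ":", nBins(object), "bins @",
      format(object@resolution, big.mark = ","), "bp;",
      sum(object@filtered), "bins below the 0.008 open-fraction filter\n")
})
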