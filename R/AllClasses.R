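#' @include AllGenerics.R
NULL

## ---------------------------------------------------------------------------
## Contact containers
## ---------------------------------------------------------------------------

#' ContactList: binned Hi-C contact pairs
#'
#' Sparse representation of binned Hi-C contacts: one record per bin pair
#' with a positive integer count. Records are canonicalised so that
#' `(chrom_a, bin_a) <= (chrom_b, bin_b)` lexicographically and duplicate
#' pairs are summed. Bin indices are 0-based; a bin `k` covers the half-open
#' genomic interval `[k * resolution, (k + 1) * resolution)`.
#'
#' @slot records data.frame with columns `chrom_a`, `bin_a`, `chrom_b`,
#'   `bin_b`, `count`.
#' @slot resolution Numeric, base pairs per bin.
#' @exportClass ContactList
setClass("ContactList",
  representation(records = "data.frame", resolution = "numeric"),
  validity = function(object) {
    r <- object@records
    need <- c("chrom_a", "bin_a", "chrom_b", "bin_b", "count")
    if (!all(need %in% names(r)))
      return(paste("records must have columns", paste(need, collapse = ", ")))
    if (length(object@resolution) != 1L || object@resolution <= 0)
      return("resolution must be a single positive number")
    if (nrow(r) > 0) {
      if (any(r$bin_a < 0) || any(r$bin_b < 0))
        return("bin indices must be non-negative")
      if (any(r$count < 1))
        return("counts must be >= 1")
      bad <- r$chrom_a > r$chrom_b |
        (r$chrom_a == r$chrom_b & r$bin_a > r$bin_b)
      if (any(bad))
        return("records must be canonicalised: (chrom_a, bin_a) <= (chrom_b, bin_b)")
    }
    TRUE
  }
)

#' ContactMatrix: dense symmetric binned contact map for one chromosome
#'
#' @slot chrom Character chromosome identifier.
#' @slot resolution Numeric, base pairs per bin.
#' @slot values Symmetric non-negative numeric matrix, `n_bins x n_bins`.
#' @slot mask Logical per-bin vector; `TRUE` marks a valid bin. Invalid bins
#'   have all-zero rows and columns.
#' @exportClass ContactMatrix
setClass("ContactMatrix",
  representation(chrom = "character", resolution = "numeric",
                 values = "matrix", mask = "logical"),
  validity = function(object) {
    v <- object@values
    if (nrow(v) != ncol(v)) return("values must be square")
    if (length(object@mask) != nrow(v))
      return("mask length must equal n_bins")
    if (any(v < 0)) return("values must be non-negative")
    if (nrow(v) > 0 && max(abs(v - t(v))) > 1e-8 * max(1, max(abs(v))))
      return("values must be symmetric")
    TRUE
  }
)

#' BalancedMatrix: Knight-Ruiz balanced contact map
#'
#' Holds the balanced matrix `diag(bias) %*% raw %*% diag(bias)` whose
#' unmasked row sums equal 1, together with the bias vector and convergence
#' state of the balancing iteration.
#'
#' @slot matrix A [ContactMatrix-class] carrying the balanced values.
#' @slot bias Per-bin positive scaling vector (`NA` for masked bins).
#' @slot converged Logical.
#' @slot iterations Integer, matrix-vector products used.
#' @exportClass BalancedMatrix
setClass("BalancedMatrix",
  representation(matrix = "ContactMatrix", bias = "numeric",
                 converged = "logical", iterations = "integer"),
  validity = function(object) {
    if (length(object@bias) != nBins(object@matrix))
      return("bias length must equal n_bins")
    TRUE
  }
)

#' RowScaledMatrix: probability-like row-normalised contact map
#'
#' Each unmasked row of a balanced matrix divided by its row sum, so that
#' unmasked rows sum to one. Not symmetric in general.
#'
#' @slot values Numeric matrix.
#' @slot mask Logical per-bin validity vector.
#' @slot chrom Character chromosome identifier.
#' @slot resolution Numeric, base pairs per bin.
#' @exportClass RowScaledMatrix
setClass("RowScaledMatrix",
  representation(values = "matrix", mask = "logical",
                 chrom = "character", resolution = "numeric"),
  validity = function(object) {
    if (length(object@mask) != nrow(object@values))
      return("mask length must equal n_bins")
    rs <- rowSums(object@values)[object@mask]
    if (length(rs) > 0 && any(abs(rs - 1) > 1e-6))
      return("unmasked rows must sum to 1")
    TRUE
  }
)

## ---------------------------------------------------------------------------
## Mixture simulation containers
## ---------------------------------------------------------------------------

#' MixtureSpec: a cell-type proportion vector on the simplex
#'
#' Ground-truth and predicted cell-type compositions both live in this
#' class. Fractions are rounded to three decimals, so the simplex constraint
#' is enforced with a 0.001 slack.
#'
#' @slot cellTypes Ordered character labels.
#' @slot fractions Numeric fractions, same length, each in `[0, 1]`.
#' @slot seed Integer seed used to draw the fractions (`NA` if not drawn).
#' @exportClass MixtureSpec
setClass("MixtureSpec",
  representation(cellTypes = "character", fractions = "numeric",
                 seed = "integer"),
  validity = function(object) {
    if (length(object@cellTypes) != length(object@fractions))
      return("cellTypes and fractions must have equal length")
    if (length(object@fractions) < 1L) return("need at least one cell type")
    if (any(object@fractions < 0)) return("fractions must be >= 0")
    if (abs(sum(object@fractions) - 1) > 0.001 + 1e-9)
      return("fractions must sum to 1 within 0.001")
    TRUE
  }
)

#' CellTypeTemplate: pooled pure-type contact profile
#'
#' The aggregated contact map of one cell type (pooled single cells or a
#' pure cell-line library), one [ContactMatrix-class] per chromosome.
#' Serves as the sampling pool for simulated single cells and bulk samples.
#'
#' @slot cellType Character label.
#' @slot matrices Named list of [ContactMatrix-class], one per chromosome.
#' @slot totalContacts Numeric grand sum of all matrices (off-diagonal
#'   entries counted once).
#' @exportClass CellTypeTemplate
setClass("CellTypeTemplate",
  representation(cellType = "character", matrices = "list",
                 totalContacts = "numeric"),
  validity = function(object) {
    if (!all(vapply(object@matrices, is, logical(1), "ContactMatrix")))
      return("matrices must be a list of ContactMatrix")
    TRUE
  }
)

#' BulkSample: a simulated bulk Hi-C library with known composition
#'
#' @slot spec The ground-truth [MixtureSpec-class].
#' @slot contacts Merged [ContactList-class] of the sample.
#' @slot provenance Named numeric vector of per-type cell counts (`N_i`) or
#'   contact counts (`M_i`) actually drawn.
#' @slot sampleId Character label.
#' @exportClass BulkSample
setClass("BulkSample",
  representation(spec = "MixtureSpec", contacts = "ContactList",
                 provenance = "numeric", sampleId = "character"))

## ---------------------------------------------------------------------------
## Model containers
## ---------------------------------------------------------------------------

#' DeconvDataset: window-pair tensors with fraction labels
#'
#' The training substrate: stitched window-pair tensors (two `w x w`
#' diagonal submatrices from two chromosomes stacked along the row axis into
#' a `2w x w` map) with the originating sample's full fraction vector as
#' label.
#'
#' @slot tensors Numeric array `(2w, w, n_tensors)`.
#' @slot labels Numeric matrix `(n_tensors, K)`, rows on the simplex.
#' @slot sampleId Character, originating sample of each tensor.
#' @slot cellTypes Character labels for the K columns of `labels`.
#' @slot meta data.frame per tensor: `chrom_a`, `chrom_b`, `start_a`,
#'   `start_b` (bin offsets of the two windows).
#' @exportClass DeconvDataset
setClass("DeconvDataset",
  representation(tensors = "array", labels = "matrix",
                 sampleId = "character", cellTypes = "character",
                 meta = "data.frame"),
  validity = function(object) {
    d <- dim(object@tensors)
    if (length(d) != 3L) return("tensors must be a 3-d array")
    if (d[1] != 2L * d[2]) return("tensor rows must be twice tensor columns")
    if (nrow(object@labels) != d[3]) return("one label row per tensor")
    if (length(object@sampleId) != d[3]) return("one sampleId per tensor")
    if (ncol(object@labels) != length(object@cellTypes))
      return("label columns must match cellTypes")
    s <- rowSums(object@labels)
    if (d[3] > 0 && any(abs(s - 1) > 0.001 + 1e-9))
      return("labels must lie on the simplex within 0.001")
    TRUE
  }
)

#' DeconvModel: the deconvolution CNN
#'
#' Four convolution layers (2x2 max-pooling after the first three), two
#' hidden dense layers and a simplex output layer, with tanh activations.
#' Parameters are stored as plain numeric matrices so that models serialise
#' as text.
#'
#' @slot config Named list of hyperparameters (see [modelConfig()]).
#' @slot params Named list of weight matrices and bias vectors.
#' @slot foldId Integer cross-validation fold this model was trained on
#'   (`NA` before training).
#' @slot history Named list of per-epoch training records.
#' @slot frozenConv Logical; `TRUE` after [freezeConv()].
#' @exportClass DeconvModel
setClass("DeconvModel",
  representation(config = "list", params = "list", foldId = "integer",
                 history = "list", frozenConv = "logical"),
  prototype(foldId = NA_integer_, history = list(), frozenConv = FALSE))

#' CVEnsemble: five-fold cross-validated model ensemble
#'
#' @slot models List of [DeconvModel-class], one per fold.
#' @slot splitAssignment Named integer vector mapping sample ids to the fold
#'   in which they were held out for validation.
#' @slot cellTypes Character labels of the output units.
#' @exportClass CVEnsemble
setClass("CVEnsemble",
  representation(models = "list", splitAssignment = "integer",
                 cellTypes = "character"),
  validity = function(object) {
    if (!all(vapply(object@models, is, logical(1), "DeconvModel")))
      return("models must be DeconvModel objects")
    folds <- sort(unique(object@splitAssignment))
    if (length(object@splitAssignment) > 0 &&
        !identical(folds, seq_along(object@models)))
      return("splitAssignment must partition samples across the folds")
    TRUE
  }
)

## ---------------------------------------------------------------------------
## Interpretation containers
## ---------------------------------------------------------------------------

#' ShapMap: expected-gradients attributions for window-pair tensors
#'
#' Per-cell-type SHAP attribution maps aligned to the coordinates of the
#' explained tensors, averaged over the contributing fold models.
#'
#' @slot values Numeric array `(2w, w, K, n_tensors)`.
#' @slot cellTypes Character labels for the K attribution maps.
#' @slot meta data.frame mirroring the explained tensors' window
#'   coordinates (`chrom_a`, `chrom_b`, `start_a`, `start_b`, `sampleId`).
#' @slot modelIds Integer ids of contributing fold models.
#' @exportClass ShapMap
setClass("ShapMap",
  representation(values = "array", cellTypes = "character",
                 meta = "data.frame", modelIds = "integer"),
  validity = function(object) {
    d <- dim(object@values)
    if (length(d) != 4L) return("values must be a 4-d array")
    if (d[3] != length(object@cellTypes))
      return("third dimension must match cellTypes")
    if (nrow(object@meta) != d[4]) return("one meta row per tensor")
    if (any(!is.finite(object@values))) return("values must be finite")
    TRUE
  }
)

#' OpenFractionTrack: per-bin open-chromatin fraction
#'
#' The fraction of each genomic bin covered by accessible-chromatin (ATAC)
#' intervals, `O_f = sum(L_r) / resolution`, clamped to `[0, 1]`. Bins with
#' `O_f < 0.008` are flagged as filtered (the boundary value 0.008 itself is
#' retained).
#'
#' @slot openFraction Numeric per-bin vector in `[0, 1]`.
#' @slot resolution Numeric bin length in bp.
#' @slot filtered Logical per-bin flag, `TRUE` when `O_f < 0.008`.
#' @slot chrom Character chromosome identifier.
#' @exportClass OpenFractionTrack
setClass("OpenFractionTrack",
  representation(openFraction = "numeric", resolution = "numeric",
                 filtered = "logical", chrom = "character"),
  validity = function(object) {
    if (length(object@filtered) != length(object@openFraction))
      return("filtered length must match openFraction")
    if (any(object@openFraction < 0 | object@openFraction > 1))
      return("open fractions must lie in [0, 1]")
    if (!identical(object@filtered, object@openFraction < 0.008))
      return("filtered flag must equal openFraction < 0.008")
    TRUE
  }
)
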