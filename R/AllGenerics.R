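#' @include decooc-package.R
NULL

#' Accessor generics
#'
#' Small accessor generics shared by the package's S4 containers.
#'
#' @param x An object.
#' @param ... Further arguments for methods.
#' @return The slot value the accessor names; see the class documentation.
#' @name accessors
#' @rdname accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chrom", function(x, ...) standardGeneric("chrom"))

#' @rdname accessors
#' @export
setGeneric("resolution", function(x, ...) standardGeneric("resolution"))

#' @rdname accessors
#' @export
setGeneric("contactValues", function(x, ...) standardGeneric("contactValues"))

#' @rdname accessors
#' @export
setGeneric("binMask", function(x, ...) standardGeneric("binMask"))

#' @rdname accessors
#' @export
setGeneric("nBins", function(x, ...) standardGeneric("nBins"))

#' @rdname accessors
#' @export
setGeneric("records", function(x, ...) standardGeneric("records"))

#' @rdname accessors
#' @export
setGeneric("biasVector", function(x, ...) standardGeneric("biasVector"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(x, ...) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setGeneric("cellTypes", function(x, ...) standardGeneric("cellTypes"))

#' @rdname accessors
#' @export
setGeneric("totalContacts", function(x, ...) standardGeneric("totalContacts"))
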