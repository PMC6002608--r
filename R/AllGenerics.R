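#' Re-exported generic from BiocGenerics
#' @importFrom BiocGenerics sizeFactors
#' @export sizeFactors
#' @name sizeFactors
#' @rdname sizeFactors-ScreenCounts-method
NULL

sizeFactors <- BiocGenerics::sizeFactors

#' @export
setGeneric("guides", function(x, ...) standardGeneric("guides"))

#' @export
setGeneric("spacers", function(x, ...) standardGeneric("spacers"))

#' @export
setGeneric("spacerLength", function(x, ...) standardGeneric("spacerLength"))

#' @export
setGeneric("guideCategories", function(x, ...) standardGeneric("guideCategories"))

#' @export
setGeneric("libraryComposition", function(x, ...)
    standardGeneric("libraryComposition"))

#' @export
setGeneric("spacerLookup", function(x, spacer, ...)
    standardGeneric("spacerLookup"))

#' @export
setGeneric("screenTruth", function(x, ...) standardGeneric("screenTruth"))

#' @export
setGeneric("dispersions", function(object, ...) standardGeneric("dispersions"))

#' @export
setGeneric("calibrationRatio", function(curve, ph, ...)
    standardGeneric("calibrationRatio"))

#' @export
setGeneric("ratioToPh", function(curve, ratio, ...)
    standardGeneric("ratioToPh"))
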