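#' @title Accessor generics
#' @description Accessor generics shared by the classes of the package.
#' @param object an object of one of the package classes
#' @param ... further arguments passed to methods
#' @return See the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixelMatrix", function(object, ...) standardGeneric("pixelMatrix"))

#' @rdname accessors
#' @export
setGeneric("pixelSpacing", function(object, ...) standardGeneric("pixelSpacing"))

#' @rdname accessors
#' @export
setGeneric("cutIndices", function(object, ...) standardGeneric("cutIndices"))

#' @rdname accessors
#' @export
setGeneric("flowValue", function(object, ...) standardGeneric("flowValue"))

#' @rdname accessors
#' @export
setGeneric("contourPolygon", function(object, ...) standardGeneric("contourPolygon"))

#' @rdname accessors
#' @export
setGeneric("lesionMask", function(object, ...) standardGeneric("lesionMask"))

#' @rdname accessors
#' @export
setGeneric("lesionDiameters", function(object, ...) standardGeneric("lesionDiameters"))

#' @rdname accessors
#' @export
setGeneric("truthMask", function(object, ...) standardGeneric("truthMask"))

#' @rdname accessors
#' @export
setGeneric("truthContour", function(object, ...) standardGeneric("truthContour"))
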