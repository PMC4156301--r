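#' @rdname accessors
#' @export
setGeneric("nRows", function(x) standardGeneric("nRows"))
#' @rdname accessors
#' @export
setGeneric("nCols", function(x) standardGeneric("nCols"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))
#' @rdname accessors
#' @export
setGeneric("imageGridOf", function(x) standardGeneric("imageGridOf"))
#' @rdname accessors
#' @export
setGeneric("geometryOf", function(x) standardGeneric("geometryOf"))
#' @rdname accessors
#' @export
setGeneric("angles", function(x) standardGeneric("angles"))
#' @rdname accessors
#' @export
setGeneric("beamType", function(x) standardGeneric("beamType"))
#' @rdname accessors
#' @export
setGeneric("nDetectors", function(x) standardGeneric("nDetectors"))
#' @rdname accessors
#' @export
setGeneric("greyValues", function(x) standardGeneric("greyValues"))
#' @rdname accessors
#' @export
setGeneric("thresholds", function(x) standardGeneric("thresholds"))

#' Accessors for tomodart objects
#'
#' Slot accessors for the core S4 classes: grid dimensions and pixel size,
#' pixel/sinogram value matrices, projection geometry components and
#' grey-level model components.
#'
#' @param x an object of one of the tomodart S4 classes.
#' @return The corresponding slot value: integers for dimensions, numeric
#'   scalars/vectors for sizes, angles and grey levels, a matrix for
#'   \code{values()}, and S4 objects for \code{imageGridOf()} /
#'   \code{geometryOf()}.
#' @name accessors
#' @examples
#' g <- imageGrid(8, pixelSize = 1)
#' nCols(g)
#' pixelSize(g)
NULL

#' @rdname accessors
#' @export
setMethod("nRows", "ImageGrid", function(x) x@nRows)
#' @rdname accessors
#' @export
setMethod("nCols", "ImageGrid", function(x) x@nCols)
#' @rdname accessors
#' @export
setMethod("pixelSize", "ImageGrid", function(x) x@pixelSize)
#' @rdname accessors
#' @export
setMethod("nRows", "TomoImage", function(x) x@grid@nRows)
#' @rdname accessors
#' @export
setMethod("nCols", "TomoImage", function(x) x@grid@nCols)
#' @rdname accessors
#' @export
setMethod("pixelSize", "TomoImage", function(x) x@grid@pixelSize)
#' @rdname accessors
#' @export
setMethod("values", "TomoImage", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("values", "Sinogram", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("imageGridOf", "TomoImage", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("imageGridOf", "TomoOperator", function(x) x@grid)
#' @rdname accessors
#' @export
setMethod("geometryOf", "Sinogram", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("geometryOf", "TomoOperator", function(x) x@geometry)
#' @rdname accessors
#' @export
setMethod("angles", "ProjectionGeometry", function(x) x@angles)
#' @rdname accessors
#' @export
setMethod("angles", "Sinogram", function(x) x@geometry@angles)
#' @rdname accessors
#' @export
setMethod("beamType", "ProjectionGeometry", function(x) x@beam)
#' @rdname accessors
#' @export
setMethod("nDetectors", "ProjectionGeometry", function(x) x@nDetectors)
#' @rdname accessors
#' @export
setMethod("greyValues", "GreyLevelModel", function(x) x@greyValues)
#' @rdname accessors
#' @export
setMethod("thresholds", "GreyLevelModel", function(x) x@thresholds)

setMethod("show", "ImageGrid", function(object) {
  cat(sprintf("ImageGrid: %d x %d pixels, pixel size %g (field of view %g)\n",
              object@nRows, object@nCols, object@pixelSize,
              object@nCols * object@pixelSize))
})

setMethod("show", "TomoImage", function(object) {
  v <- object@values
  cat(sprintf("TomoImage: %d x %d pixels @ %g, values in [%g, %g]\n",
              nrow(v), ncol(v), object@grid@pixelSize, min(v), max(v)))
})

setMethod("show", "ProjectionGeometry", function(object) {
  cat(sprintf(
    "ProjectionGeometry: %s beam, %d angles over %g deg (missing wedge %g deg), %d detector bins @ %g\n",
    object@beam, length(object@angles), object@angularRange,
    object@missingWedge, object@nDetectors, object@detectorPixelSize))
  if (identical(object@beam, "fan"))
    cat(sprintf("  source-object %g, source-detector %g\n",
                object@sourceObjectDistance, object@sourceDetectorDistance))
})

setMethod("show", "Sinogram", function(object) {
  cat(sprintf("Sinogram: %d angles x %d bins, values in [%g, %g]\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "GreyLevelModel", function(object) {
  cat("GreyLevelModel:\n  grey values:",
      paste(format(object@greyValues), collapse = ", "),
      "\n  thresholds: ",
      paste(format(object@thresholds), collapse = ", "), "\n")
})

setMethod("show", "PixelPartition", function(object) {
  cat(sprintf(
    "PixelPartition: %d non-fixed (%d boundary), %d fixed of %d pixels\n",
    length(object@nonFixed), length(object@boundary),
    length(object@fixed), object@nPixels))
})

setMethod("show", "TomoOperator", function(object) {
  cat(sprintf(
    "TomoOperator (Joseph): %d rays x %d pixels, %d stored weights\n",
    nrow(object@W), ncol(object@W), length(object@W@x)))
})
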