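#' @import methods
#' @importFrom Matrix sparseMatrix t colSums rowSums
NULL

#' Square reconstruction grid
#'
#' A square pixel raster centred on the rotation axis. The physical field
#' of view is \code{nCols * pixelSize} length units in each direction; pixel
#' values are interpreted as samples at pixel centres. Coarsening a grid
#' (fewer, larger pixels) preserves the field of view.
#'
#' @slot nRows,nCols integer, numbers of rows and columns (must be equal).
#' @slot pixelSize positive numeric, physical size of one pixel.
#' @export
setClass("ImageGrid",
  representation(nRows = "integer", nCols = "integer", pixelSize = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@nRows) != 1L || length(object@nCols) != 1L ||
        is.na(object@nRows) || is.na(object@nCols))
      msg <- c(msg, "nRows and nCols must be single non-missing integers")
    else {
      if (object@nRows != object@nCols)
        msg <- c(msg, "grid must be square (nRows == nCols)")
      if (object@nRows < 1L)
        msg <- c(msg, "grid side must be >= 1")
    }
    if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
        object@pixelSize <= 0)
      msg <- c(msg, "pixelSize must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Real-valued image on a grid
#'
#' An attenuation map: one finite real value per pixel of an
#' \linkS4class{ImageGrid}, stored as an \code{nRows x nCols} matrix.
#'
#' @slot grid an \linkS4class{ImageGrid}.
#' @slot values numeric matrix of pixel values.
#' @export
setClass("TomoImage",
  representation(grid = "ImageGrid", values = "matrix"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v))
      msg <- c(msg, "values must be numeric")
    if (nrow(v) != object@grid@nRows || ncol(v) != object@grid@nCols)
      msg <- c(msg, "values dimensions must match the grid")
    if (any(!is.finite(v)))
      msg <- c(msg, "values must be finite")
    if (length(msg)) msg else TRUE
  })

#' Projection geometry
#'
#' Equiangular parallel- or fan-beam acquisition geometry. Angles are in
#' radians, counter-clockwise from the x-axis; an optional missing wedge
#' is carved out of the top of the angular range. For fan beam the source
#' rotates at \code{sourceObjectDistance} from the rotation axis and the
#' (flat, centred) detector at \code{sourceDetectorDistance} from the
#' source.
#'
#' @slot beam \code{"parallel"} or \code{"fan"}.
#' @slot angles numeric vector of projection angles (radians), strictly
#'   increasing.
#' @slot nDetectors integer, number of detector bins.
#' @slot detectorPixelSize positive numeric, detector bin width.
#' @slot sourceObjectDistance,sourceDetectorDistance numeric; positive and
#'   ordered for fan beam, \code{NA} for parallel beam.
#' @slot angularRange numeric, nominal angular range in degrees.
#' @slot missingWedge numeric, width of the missing wedge in degrees.
#' @export
setClass("ProjectionGeometry",
  representation(beam = "character", angles = "numeric",
                 nDetectors = "integer", detectorPixelSize = "numeric",
                 sourceObjectDistance = "numeric",
                 sourceDetectorDistance = "numeric",
                 angularRange = "numeric", missingWedge = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!(object@beam %in% c("parallel", "fan")))
      msg <- c(msg, "beam must be 'parallel' or 'fan'")
    if (length(object@angles) < 1L || any(!is.finite(object@angles)))
      msg <- c(msg, "at least one finite angle is required")
    if (length(object@angles) > 1L && any(diff(object@angles) <= 0))
      msg <- c(msg, "angles must be strictly increasing")
    if (object@nDetectors < 1L)
      msg <- c(msg, "nDetectors must be >= 1")
    if (!is.finite(object@detectorPixelSize) || object@detectorPixelSize <= 0)
      msg <- c(msg, "detectorPixelSize must be positive")
    if (object@missingWedge < 0)
      msg <- c(msg, "missingWedge must be >= 0")
    if (object@missingWedge >= object@angularRange)
      msg <- c(msg, "missingWedge must be smaller than angularRange")
    if (identical(object@beam, "fan")) {
      dso <- object@sourceObjectDistance
      dsd <- object@sourceDetectorDistance
      if (!is.finite(dso) || !is.finite(dsd) || dso <= 0 || dsd <= dso)
        msg <- c(msg,
          "fan beam requires sourceDetectorDistance > sourceObjectDistance > 0")
    }
    if (length(msg)) msg else TRUE
  })

#' Sinogram (measured line integrals)
#'
#' Line-integral data on a \linkS4class{ProjectionGeometry}: one row per
#' projection angle, one column per detector bin.
#'
#' @slot geometry a \linkS4class{ProjectionGeometry}.
#' @slot values numeric matrix, \code{n_angles x n_detectors}.
#' @export
setClass("Sinogram",
  representation(geometry = "ProjectionGeometry", values = "matrix"),
  validity = function(object) {
    msg <- character()
    g <- object@geometry
    if (nrow(object@values) != length(g@angles) ||
        ncol(object@values) != g@nDetectors)
      msg <- c(msg, "values must be n_angles x n_detectors")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "sinogram values must be finite")
    if (length(msg)) msg else TRUE
  })

#' Grey-level prior for discrete tomography
#'
#' Ordered grey values rho_1 < ... < rho_L with segmentation thresholds
#' tau_1 < ... < tau_{L-1} interleaved (rho_i < tau_i < rho_{i+1}). A pixel
#' with value in the half-open interval (tau_{i-1}, tau_i] segments to
#' rho_i; by default thresholds are grey-value midpoints (a global
#' threshold).
#'
#' @slot greyValues strictly increasing numeric vector, length >= 2.
#' @slot thresholds strictly increasing numeric vector, length L - 1.
#' @export
setClass("GreyLevelModel",
  representation(greyValues = "numeric", thresholds = "numeric"),
  validity = function(object) {
    rho <- object@greyValues; tau <- object@thresholds
    msg <- character()
    if (length(rho) < 2L)
      msg <- c(msg, "at least two grey values are required")
    if (any(diff(rho) <= 0))
      msg <- c(msg, "grey values must be strictly increasing")
    if (length(tau) != length(rho) - 1L)
      msg <- c(msg, "need exactly one threshold between consecutive grey values")
    else if (any(tau <= rho[-length(rho)]) || any(tau >= rho[-1L]))
      msg <- c(msg, "each threshold must lie strictly between its grey values")
    if (length(msg)) msg else TRUE
  })

#' Fixed / non-fixed pixel partition
#'
#' The DART partition of grid pixels: the non-fixed set U (boundary pixels
#' plus a random sample of non-boundary pixels) receives algebraic updates;
#' the fixed set F keeps its segmented grey values. Pixels are stored as
#' column-major linear indices into the grid.
#'
#' @slot nonFixed integer indices of U.
#' @slot fixed integer indices of F (complement of U).
#' @slot boundary integer indices of boundary pixels, a subset of U.
#' @slot nPixels total pixel count of the grid.
#' @export
setClass("PixelPartition",
  representation(nonFixed = "integer", fixed = "integer",
                 boundary = "integer", nPixels = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(intersect(object@fixed, object@nonFixed)) > 0L)
      msg <- c(msg, "fixed and non-fixed sets must be disjoint")
    if (length(object@fixed) + length(object@nonFixed) != object@nPixels)
      msg <- c(msg, "fixed and non-fixed sets must cover the grid")
    if (!all(object@boundary %in% object@nonFixed))
      msg <- c(msg, "boundary pixels must be non-fixed")
    if (length(msg)) msg else TRUE
  })

#' Joseph projection operator
#'
#' A linear operator implementing the tomographic system matrix W by
#' Joseph's ray-driven method: forward projection maps an image to its
#' sinogram, back projection applies the exact transpose. The sparse
#' matrix is assembled once per (grid, geometry) pair; rays that miss the
#' grid entirely have zero rows and are inert under SIRT scaling.
#'
#' @slot grid the reconstruction \linkS4class{ImageGrid}.
#' @slot geometry the \linkS4class{ProjectionGeometry}.
#' @slot W sparse system matrix, (n_angles * n_detectors) x n_pixels, with
#'   rays ordered angle-major and pixels column-major.
#' @export
setClass("TomoOperator",
  representation(grid = "ImageGrid", geometry = "ProjectionGeometry",
                 W = "Matrix"))
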