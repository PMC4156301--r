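## File formats.
##
## Integer label images (phantoms, segmentations) go to PNG (8-bit) or
## TIFF (16-bit) and round-trip exactly. Continuous reconstructions use a
## raw little-endian float32 dialect: <path> holds the pixel values in
## column-major order and <path>.json a sidecar with the grid metadata.
## Sinograms use the same raw dialect with the full projection geometry in
## the sidecar.

.imageFormat <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (ext %in% c("png")) return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  if (ext %in% c("raw", "f32")) return("raw")
  stop("unknown image file extension: .", ext,
       " (supported: .png, .tif/.tiff, .raw/.f32)")
}

#' Write an image to disk
#'
#' PNG stores integer values 0-255 (8-bit grey), TIFF integer values
#' 0-65535 (16-bit grey); both reproduce label images exactly but carry no
#' pixel size. The raw float32 dialect (.raw/.f32) stores any values
#' losslessly at single precision together with a JSON sidecar
#' (\code{<path>.json}) holding \code{n_rows}, \code{n_cols} and
#' \code{pixel_size}.
#'
#' @param image a \linkS4class{TomoImage}.
#' @param path output file; the extension selects the format.
#' @return \code{path}, invisibly.
#' @export
writeImage <- function(image, path) {
  fmt <- .imageFormat(path)
  v <- image@values
  if (fmt %in% c("png", "tiff")) {
    maxv <- if (fmt == "png") 255 else 65535
    if (any(v != round(v)) || any(v < 0) || any(v > maxv))
      stop("integer formats require integer values in [0, ", maxv,
           "]; use the raw float dialect for continuous images")
    if (fmt == "png") png::writePNG(v / maxv, path)
    else tiff::writeTIFF(v / maxv, path, bits.per.sample = 16L)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(v), con, size = 4L, endian = "little")
    jsonlite::write_json(
      list(n_rows = nrow(v), n_cols = ncol(v),
           pixel_size = image@grid@pixelSize),
      paste0(path, ".json"), auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}

## collapse an RGB(A) array read from PNG/TIFF to one grey channel
.greyChannel <- function(a) {
  if (is.matrix(a)) return(a)
  if (length(dim(a)) == 3L) {
    g <- a[, , 1L]
    for (ch in seq_len(min(3L, dim(a)[3L]))[-1L])
      if (any(a[, , ch] != g))
        stop("image is not greyscale")
    return(g)
  }
  stop("unsupported image layout")
}

#' Read an image from disk
#'
#' Inverse of \code{\link{writeImage}}. Integer formats do not store a
#' pixel size, so one can be supplied; the raw dialect takes everything
#' from its sidecar.
#'
#' @param path file written by \code{\link{writeImage}} (or any greyscale
#'   PNG/TIFF).
#' @param pixelSize pixel size to attach when reading PNG/TIFF.
#' @return A \linkS4class{TomoImage}.
#' @export
readImage <- function(path, pixelSize = 1) {
  fmt <- .imageFormat(path)
  if (fmt == "png") {
    v <- round(.greyChannel(png::readPNG(path)) * 255)
    return(tomoImage(v, imageGrid(dim(v), pixelSize)))
  }
  if (fmt == "tiff") {
    v <- round(.greyChannel(tiff::readTIFF(path)) * 65535)
    return(tomoImage(v, imageGrid(dim(v), pixelSize)))
  }
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(meta$n_rows) || is.null(meta$n_cols))
    stop("sidecar is missing n_rows/n_cols")
  nVal <- meta$n_rows * meta$n_cols
  if (file.info(path)$size != 4L * nVal)
    stop("raw payload size does not match the sidecar dimensions")
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = nVal, size = 4L, endian = "little")
  ps <- if (is.null(meta$pixel_size)) 1 else meta$pixel_size
  tomoImage(matrix(v, meta$n_rows, meta$n_cols),
            imageGrid(meta$n_rows, ps))
}

#' Write a sinogram to disk
#'
#' Raw little-endian float32 payload (values in angle-major, column-major
#' matrix order) plus a JSON sidecar (\code{<path>.json}) carrying the
#' full projection geometry, so a sinogram round-trips losslessly
#' including its angle list and fan-beam distances.
#'
#' @param sino a \linkS4class{Sinogram}.
#' @param path output file (.raw/.f32).
#' @return \code{path}, invisibly.
#' @export
writeSinogram <- function(sino, path) {
  g <- sino@geometry
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(sino@values), con, size = 4L, endian = "little")
  jsonlite::write_json(
    list(beam = g@beam, angles = g@angles, n_detectors = g@nDetectors,
         detector_pixel_size = g@detectorPixelSize,
         source_object_distance = g@sourceObjectDistance,
         source_detector_distance = g@sourceDetectorDistance,
         angular_range = g@angularRange, missing_wedge = g@missingWedge),
    paste0(path, ".json"), auto_unbox = TRUE, digits = I(17), na = "null")
  invisible(path)
}

#' Read a sinogram from disk
#'
#' @param path file written by \code{\link{writeSinogram}}.
#' @return A \linkS4class{Sinogram}.
#' @export
readSinogram <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (is.null(meta$beam))
    stop("sidecar is missing the beam type")
  toNum <- function(x) if (is.null(x) || is.na(x)) NA_real_ else as.numeric(x)
  geom <- new("ProjectionGeometry", beam = meta$beam,
              angles = as.numeric(meta$angles),
              nDetectors = as.integer(meta$n_detectors),
              detectorPixelSize = as.numeric(meta$detector_pixel_size),
              sourceObjectDistance = toNum(meta$source_object_distance),
              sourceDetectorDistance = toNum(meta$source_detector_distance),
              angularRange = as.numeric(meta$angular_range),
              missingWedge = as.numeric(meta$missing_wedge))
  nVal <- length(geom@angles) * geom@nDetectors
  if (file.info(path)$size != 4L * nVal)
    stop("raw payload size does not match the sidecar geometry")
  con <- file(path, "rb")
  on.exit(close(con))
  v <- readBin(con, "numeric", n = nVal, size = 4L, endian = "little")
  sinogram(matrix(v, length(geom@angles), geom@nDetectors), geom)
}
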