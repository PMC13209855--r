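#' Micrograph container
#'
#' A grayscale micrograph is an integer intensity matrix (rows x columns,
#' pixel centers at integer 1-based coordinates) plus the instrument
#' metadata the sizing pipeline needs: the height of the bottom databar
#' strip and the scale-bar calibration (physical length of a known pixel
#' run).
#'
#' @param data integer matrix of intensities, row-major image
#' @param bit_depth bits per pixel (8 or 16)
#' @param databar_height height in pixels of the instrument databar at the
#'   bottom of the frame (0 if already cropped)
#' @param scalebar_px length of the scale bar in pixels
#' @param scalebar_um physical length of the scale bar in micrometers
#' @return an object of class `micrograph`
#' @export
micrograph <- function(data, bit_depth = 8, databar_height = 0,
                       scalebar_px = 229, scalebar_um = 20) {
  if (!is.matrix(data)) stop_cap("`data` must be a matrix")
  maxv <- 2^bit_depth - 1
  if (any(data < 0) || any(data > maxv)) {
    stop_cap("intensities outside the declared ", bit_depth, "-bit range")
  }
  structure(
    list(data = data, bit_depth = bit_depth,
         databar_height = databar_height,
         scalebar_px = scalebar_px, scalebar_um = scalebar_um),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  cat(sprintf("<micrograph> %d x %d px, %d-bit, databar %d px, scale %g um / %d px\n",
              nrow(x$data), ncol(x$data), x$bit_depth, x$databar_height,
              x$scalebar_um, x$scalebar_px))
  invisible(x)
}

#' @export
dim.micrograph <- function(x) dim(x$data)

#' Write a micrograph as an 8-bit grayscale TIFF
#'
#' @param img a [micrograph]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_micrograph <- function(img, path) {
  stopifnot(inherits(img, "micrograph"))
  maxv <- 2^img$bit_depth - 1
  tiff::writeTIFF(img$data / maxv, path, bits.per.sample = 8L,
                  compression = "none")
  invisible(path)
}

#' Read a grayscale TIFF or PNG as a micrograph
#'
#' Multi-channel images are converted to grayscale by channel averaging.
#' Scale-bar and databar metadata are not stored in the files the pipeline
#' consumes, so they are supplied by the caller.
#'
#' @param path image file (.tif/.tiff/.png)
#' @inheritParams micrograph
#' @return a [micrograph] with 8-bit intensities
#' @export
read_micrograph <- function(path, databar_height = 0,
                            scalebar_px = 229, scalebar_um = 20) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop_cap("reading PNG requires the 'png' package")
    }
    png::readPNG(path)
  } else {
    stop_cap("unsupported image format: .", ext)
  }
  if (length(dim(arr)) == 3) arr <- apply(arr, c(1, 2), mean)
  micrograph(round(arr * 255), bit_depth = 8,
             databar_height = databar_height,
             scalebar_px = scalebar_px, scalebar_um = scalebar_um)
}
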