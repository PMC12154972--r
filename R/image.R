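#' Calibrated grayscale image
#'
#' Container for a 2-D intensity raster together with its physical pixel
#' size and acquisition modality. Intensities live in \[0, 1\]; the pixel
#' size is micrometres per pixel for light microscopy (`"LM"`) and
#' nanometres per pixel for transmission electron microscopy (`"TEM"`).
#'
#' Pixel coordinates throughout the package are continuous `(row, col)`
#' pairs with pixel centres at integer positions `1..nrow`, `1..ncol`.
#'
#' @param intensities numeric matrix of gray levels in \[0, 1\].
#' @param pixel_size physical length per pixel (> 0); um for LM, nm for TEM.
#' @param modality `"LM"` or `"TEM"`.
#' @return An object of class `calibrated_image`.
#' @export
calibrated_image <- function(intensities, pixel_size, modality = c("LM", "TEM")) {
  modality <- match.arg(modality)
  if (!is.matrix(intensities) || !is.numeric(intensities) ||
      nrow(intensities) < 1L || ncol(intensities) < 1L)
    stop("intensities must be a non-empty numeric matrix")
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || !is.finite(pixel_size) ||
      pixel_size <= 0)
    stop("pixel_size must be a single positive number")
  rng <- range(intensities)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("intensities must lie in [0, 1]")
  structure(list(intensities = intensities, pixel_size = pixel_size,
                 modality = modality),
            class = "calibrated_image")
}

#' @export
print.calibrated_image <- function(x, ...) {
  cat(sprintf("<calibrated_image %s %d x %d px, %g %s/px>\n",
              x$modality, nrow(x$intensities), ncol(x$intensities),
              x$pixel_size, if (x$modality == "LM") "um" else "nm"))
  invisible(x)
}

#' Region-of-interest mask
#'
#' Boolean raster congruent with the image it annotates, optionally tagged
#' with the dermis layer it delimits.
#'
#' @param member logical matrix; `TRUE` marks ROI membership.
#' @param layer_label one of `"papillary"`, `"reticular"`, `"none"`.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(member, layer_label = c("none", "papillary", "reticular")) {
  layer_label <- match.arg(layer_label)
  if (!is.matrix(member) || !is.logical(member))
    stop("member must be a logical matrix")
  structure(list(member = member, layer_label = layer_label),
            class = "region_mask")
}

#' Full-frame ROI for an image
#' @param image a `calibrated_image`.
#' @param layer_label layer tag for the mask.
#' @return A `region_mask` covering every pixel.
#' @export
full_roi <- function(image, layer_label = "none") {
  region_mask(matrix(TRUE, nrow(image$intensities), ncol(image$intensities)),
              layer_label)
}

#' Ordered polyline in pixel coordinates
#'
#' @param points numeric matrix with two columns `(row, col)` and at least
#'   two rows; consecutive points must be distinct.
#' @return A `polyline` object (a matrix with class attribute).
#' @export
polyline <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2L || nrow(points) < 2L || !is.numeric(points))
    stop("a polyline needs a numeric n x 2 matrix of (row, col) points, n >= 2")
  d <- rowSums((points[-1L, , drop = FALSE] - points[-nrow(points), , drop = FALSE])^2)
  if (any(d == 0))
    stop("consecutive polyline points must be distinct")
  colnames(points) <- c("row", "col")
  structure(points, class = c("polyline", "matrix"))
}

# arc length of a polyline in pixel units
polyline_arc_length <- function(pl) {
  seg <- diff(unclass(pl))
  sum(sqrt(rowSums(seg^2)))
}

# straight-line distance between first and last point, pixel units
polyline_chord <- function(pl) {
  p <- unclass(pl)
  sqrt(sum((p[nrow(p), ] - p[1L, ])^2))
}

#' Bilinear intensity sampling
#'
#' Samples image intensities at continuous `(row, col)` positions by
#' bilinear interpolation; positions are clamped to the image border.
#'
#' @param image a `calibrated_image` or a plain numeric matrix.
#' @param rows,cols numeric vectors of equal length, continuous pixel
#'   coordinates (pixel centres at integers).
#' @return Numeric vector of interpolated intensities.
#' @export
bilinear_sample <- function(image, rows, cols) {
  m <- if (inherits(image, "calibrated_image")) image$intensities else image
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(rows, 1), nr)
  c <- pmin(pmax(cols, 1), nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  i00 <- m[cbind(r0, c0)];         i01 <- m[cbind(r0, c0 + 1L)]
  i10 <- m[cbind(r0 + 1L, c0)];    i11 <- m[cbind(r0 + 1L, c0 + 1L)]
  i00 * (1 - fr) * (1 - fc) + i01 * (1 - fr) * fc +
    i10 * fr * (1 - fc) + i11 * fr * fc
}

# quantize intensities to the 16-bit grid used on disk, so in-memory
# measurements and disk round trips see identical rasters
quantize16 <- function(x) round(pmin(pmax(x, 0), 1) * 65535) / 65535

#' Write a calibrated image to disk
#'
#' 16-bit grayscale TIFF (`.tif`/`.tiff`) or PNG (`.png`). Calibration is
#' not embedded in the raster file; it travels in the JSON sidecar written
#' by [generate_cohort()] or must be supplied by the reader.
#'
#' @param image a `calibrated_image`.
#' @param path output path; extension selects the format.
#' @export
write_image <- function(image, path) {
  x <- quantize16(image$intensities)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(x, path, bits.per.sample = 16L)
  } else if (ext == "png") {
    png::writePNG(x, path)
  } else stop("unsupported image format: ", ext)
  invisible(path)
}

#' Read a calibrated image from disk
#'
#' @param path TIFF or PNG file.
#' @param pixel_size physical length per pixel (um for LM, nm for TEM).
#' @param modality `"LM"` or `"TEM"`.
#' @return A `calibrated_image`.
#' @export
read_image <- function(path, pixel_size, modality = c("LM", "TEM")) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
       else if (ext == "png") png::readPNG(path)
       else stop("unsupported image format: ", ext)
  if (length(dim(x)) == 3L) {
    # RGB input is reduced to luminance; the classification criterion is a
    # single intensity threshold
    x <- 0.2126 * x[, , 1L] + 0.7152 * x[, , 2L] + 0.0722 * x[, , 3L]
  }
  calibrated_image(x, pixel_size, match.arg(modality))
}
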