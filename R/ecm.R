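#' Select an intensity threshold separating stained from unstained pixels
#'
#' The stained (eosin, fibrillar) phase is dark and the unstained
#' (amorphous) phase is bright. The threshold is either supplied verbatim
#' (`method = "fixed"`, modelling an expert-chosen level) or computed by
#' Otsu's between-class-variance criterion on the ROI histogram
#' (`method = "otsu"`, the automated default for synthetic data).
#'
#' @param image a `calibrated_image`.
#' @param roi a `region_mask`; defaults to the full frame.
#' @param method `"otsu"` or `"fixed"`.
#' @param t threshold for `method = "fixed"`, a gray level in (0, 1).
#' @return A single gray level in (0, 1).
#' @export
select_threshold <- function(image, roi = full_roi(image),
                             method = c("otsu", "fixed"), t = NULL) {
  method <- match.arg(method)
  check_roi(image, roi)
  if (method == "fixed") {
    if (is.null(t) || !is.numeric(t) || length(t) != 1L || t <= 0 || t >= 1)
      stop("method = 'fixed' needs a threshold t in (0, 1)")
    return(t)
  }
  v <- image$intensities[roi$member]
  if (diff(range(v)) == 0)
    stop("constant-intensity ROI: Otsu thresholding has no separable classes")
  # EBImage expects a matrix; the ROI values are re-shaped into one column
  EBImage::otsu(matrix(v, ncol = 1L), range = c(0, 1), levels = 256L)
}

check_roi <- function(image, roi) {
  stopifnot(inherits(image, "calibrated_image"), inherits(roi, "region_mask"))
  if (!identical(dim(roi$member), dim(image$intensities)))
    stop("ROI mask shape does not match the image")
  if (!any(roi$member))
    stop("ROI is empty")
  invisible(TRUE)
}

#' Classify amorphous (unstained) pixels
#'
#' A pixel is amorphous iff it lies in the ROI and its intensity strictly
#' exceeds the threshold; pixels outside the ROI are never members.
#'
#' @inheritParams select_threshold
#' @param threshold gray level in (0, 1).
#' @return A `region_mask` of amorphous pixels (layer label inherited from
#'   the ROI).
#' @export
classify_amorphous <- function(image, roi = full_roi(image), threshold) {
  check_roi(image, roi)
  if (threshold <= 0 || threshold >= 1)
    stop("threshold must lie in (0, 1)")
  region_mask(roi$member & image$intensities > threshold, roi$layer_label)
}

#' Amorphous-ECM percentage of a dermal ROI
#'
#' Counts unstained (amorphous) and stained (fibrillar) pixels inside the
#' ROI and reports the amorphous percentage of the total connective tissue,
#' `100 * unstained / (unstained + stained)`. Both counts are returned so
#' the unstained-to-stained ratio is recoverable as well.
#'
#' @inheritParams classify_amorphous
#' @return A list of class `amorphous_result`: `unstained_count`,
#'   `stained_count`, `amorphous_pct`, `threshold_used`.
#' @examples
#' sec <- generate_he_section(synth_histology_params(target_amorphous_fraction = 0.25))
#' amorphous_percentage(sec$image, threshold = select_threshold(sec$image))
#' @export
amorphous_percentage <- function(image, roi = full_roi(image), threshold) {
  amask <- classify_amorphous(image, roi, threshold)
  unstained <- sum(amask$member)
  total <- sum(roi$member)
  structure(list(unstained_count = unstained,
                 stained_count = total - unstained,
                 amorphous_pct = 100 * unstained / total,
                 threshold_used = threshold),
            class = "amorphous_result")
}

#' @export
print.amorphous_result <- function(x, ...) {
  cat(sprintf("amorphous ECM: %.2f%% (%d unstained / %d ROI px, threshold %.4f)\n",
              x$amorphous_pct, x$unstained_count,
              x$unstained_count + x$stained_count, x$threshold_used))
  invisible(x)
}
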