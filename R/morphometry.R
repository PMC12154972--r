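#' Linearity (tortuosity) index of a bundle centerline
#'
#' Ratio of the real path length of the bundle profile to the straight-line
#' distance between its endpoints. A perfectly straight bundle scores 1;
#' higher values mean higher tortuosity.
#'
#' @param centerline a [polyline()].
#' @return Dimensionless ratio >= 1.
#' @examples
#' linearity_index(polyline(cbind(c(0, 0, 0), c(0, 5, 9))))  # 1
#' @export
linearity_index <- function(centerline) {
  if (!inherits(centerline, "polyline")) centerline <- polyline(centerline)
  chord <- polyline_chord(centerline)
  if (chord == 0)
    stop("coincident endpoints: the chord of a closed path is zero, ",
         "linearity index undefined")
  polyline_arc_length(centerline) / chord
}

# 1-D Gaussian smoothing with replicated-edge padding
smooth_gauss <- function(x, sigma) {
  if (sigma <= 0) return(x)
  h <- max(1L, ceiling(3 * sigma))
  kk <- stats::dnorm(-h:h, sd = sigma)
  kk <- kk / sum(kk)
  xp <- c(rep(x[1L], h), x, rep(x[length(x)], h))
  as.numeric(stats::filter(xp, kk, sides = 2L))[(h + 1L):(h + length(x))]
}

# resample a polyline at equal arc-length steps; returns (row, col) matrix
# and the step actually used (pixel units)
resample_polyline <- function(pl, step_px) {
  p <- unclass(pl)
  seg <- sqrt(rowSums(diff(p)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  n <- max(2L, floor(total / step_px) + 1L)
  s <- seq(0, total, length.out = n)
  rows <- stats::approx(cum, p[, 1L], xout = s)$y
  cols <- stats::approx(cum, p[, 2L], xout = s)$y
  list(points = cbind(rows, cols), s = s, step = s[2L] - s[1L])
}

#' Intensity profile along a straight transect
#'
#' Samples the image by bilinear interpolation at sub-pixel steps along the
#' segment from `p0` to `p1` (both `(row, col)` pixel coordinates).
#'
#' @param image a `calibrated_image` (TEM modality expected).
#' @param p0,p1 numeric `(row, col)` endpoints.
#' @param step_px sampling step along the line, <= 1 pixel (default 0.5).
#' @return A `transect_profile`: `intensities`, `position_nm`, `step_nm`,
#'   `pixel_size_nm`, `endpoints`.
#' @export
extract_transect <- function(image, p0, p1, step_px = 0.5) {
  stopifnot(step_px > 0, step_px <= 1)
  len_px <- sqrt(sum((p1 - p0)^2))
  n <- max(2L, floor(len_px / step_px) + 1L)
  f <- seq(0, 1, length.out = n)
  rows <- p0[1L] + f * (p1[1L] - p0[1L])
  cols <- p0[2L] + f * (p1[2L] - p0[2L])
  step_nm <- len_px / (n - 1L) * image$pixel_size
  transect_profile(bilinear_sample(image, rows, cols), step_nm,
                   pixel_size_nm = image$pixel_size,
                   endpoints = rbind(p0, p1))
}

#' Construct a transect profile from raw samples
#'
#' @param intensities sampled gray levels (>= 16 samples).
#' @param step_nm physical distance between consecutive samples.
#' @param pixel_size_nm nm per pixel of the source image (defaults to
#'   `2 * step_nm`, i.e. half-pixel sampling).
#' @param endpoints optional 2 x 2 matrix of `(row, col)` endpoints.
#' @return A `transect_profile` object.
#' @export
transect_profile <- function(intensities, step_nm,
                             pixel_size_nm = 2 * step_nm, endpoints = NULL) {
  if (length(intensities) < 16L)
    stop("a transect profile needs at least 16 samples")
  stopifnot(step_nm > 0, pixel_size_nm > 0, step_nm <= pixel_size_nm + 1e-12)
  structure(list(intensities = as.numeric(intensities),
                 position_nm = (seq_along(intensities) - 1) * step_nm,
                 step_nm = step_nm, pixel_size_nm = pixel_size_nm,
                 endpoints = endpoints),
            class = "transect_profile")
}

#' Segment fibrils on a transect profile
#'
#' Smooths the profile (Gaussian, `sigma_px` pixels), then marks fibril
#' intervals as maximal runs below the half-depth level between the bright
#' gap baseline and the dark fibril minimum, with sub-sample edge
#' localization by linear interpolation. Fibril diameters are interval
#' widths; interfibrillar distances are the edge-to-edge bright intervals
#' between consecutive fibrils. Intervals truncated by the profile ends are
#' discarded (both edges must be observed).
#'
#' @param profile a [transect_profile()].
#' @param sigma_px smoothing SD in pixels (default 1).
#' @return A `fibril_segmentation`: `intervals_nm` (n x 2 matrix),
#'   `diameters_nm`, `gaps_nm`, `level`.
#' @export
measure_fibrils <- function(profile, sigma_px = 1) {
  stopifnot(inherits(profile, "transect_profile"))
  sig <- sigma_px * profile$pixel_size_nm / profile$step_nm
  y <- smooth_gauss(profile$intensities, sig)
  bright <- stats::quantile(y, 0.95, names = FALSE)
  dark <- min(y)
  if (bright - dark < 0.05)
    stop("no fibrils detected: profile contrast too low")
  level <- (bright + dark) / 2
  below <- y < level
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- profile$position_nm
  iv <- NULL
  for (j in which(r$values)) {
    a <- starts[j]; b <- ends[j]
    if (a == 1L || b == length(y)) next  # truncated by the profile end
    # sub-sample crossings on each flank
    fa <- (y[a - 1L] - level) / (y[a - 1L] - y[a])
    left <- pos[a - 1L] + fa * (pos[a] - pos[a - 1L])
    fb <- (y[b] - level) / (y[b] - y[b + 1L])
    right <- pos[b] + fb * (pos[b + 1L] - pos[b])
    iv <- rbind(iv, c(left, right))
  }
  if (is.null(iv))
    stop("no fibrils detected on the transect")
  diameters <- iv[, 2L] - iv[, 1L]
  gaps <- if (nrow(iv) > 1L) iv[-1L, 1L] - iv[-nrow(iv), 2L] else numeric(0)
  structure(list(intervals_nm = iv, diameters_nm = diameters,
                 gaps_nm = gaps, level = level),
            class = "fibril_segmentation")
}

#' Collagen bundle thickness from perpendicular probes
#'
#' Casts `n_probes` transects perpendicular to the centerline at evenly
#' spaced stations, measures the dark-band width on each by the half-depth
#' criterion (midpoint between the local bright background and the band
#' minimum), and returns the mean width in nm. Probes that exit the image
#' or find no dark band are dropped; more than 50\% dropped is an error.
#'
#' @param image a `calibrated_image` (TEM).
#' @param centerline a [polyline()] tracing the bundle axis.
#' @param n_probes number of perpendicular probes (default 20).
#' @param sigma_px profile smoothing SD in pixels.
#' @return Mean bundle thickness in nm, with attribute `widths_nm` giving
#'   the per-probe widths.
#' @export
bundle_thickness <- function(image, centerline, n_probes = 20L, sigma_px = 1) {
  if (!inherits(centerline, "polyline")) centerline <- polyline(centerline)
  m <- image$intensities
  nr <- nrow(m); nc <- ncol(m)
  rs <- resample_polyline(centerline, 0.5)
  total <- rs$s[length(rs$s)]
  stations <- (seq_len(n_probes) - 0.5) / n_probes * total
  widths <- rep(NA_real_, n_probes)
  for (i in seq_len(n_probes)) {
    s0 <- stations[i]
    j <- findInterval(s0, rs$s, all.inside = TRUE)
    ctr <- rs$points[j, ] + (s0 - rs$s[j]) / rs$step * (rs$points[j + 1L, ] - rs$points[j, ])
    tang <- rs$points[min(j + 2L, nrow(rs$points)), ] - rs$points[max(j - 2L, 1L), ]
    tang <- tang / sqrt(sum(tang^2))
    nvec <- c(-tang[2L], tang[1L])
    # longest symmetric probe that stays inside the raster
    lim <- function(ctr_c, dir_c, lo, hi) {
      if (abs(dir_c) < 1e-12) return(Inf)
      max((lo - ctr_c) / dir_c, (hi - ctr_c) / dir_c)
    }
    half_px <- min(lim(ctr[1L], nvec[1L], 1, nr), lim(ctr[1L], -nvec[1L], 1, nr),
                   lim(ctr[2L], nvec[2L], 1, nc), lim(ctr[2L], -nvec[2L], 1, nc))
    half_px <- floor(half_px)
    if (half_px < 4) next
    nsamp <- 2L * floor(half_px / 0.5) + 1L
    f <- seq(-half_px, half_px, length.out = nsamp)
    rows <- ctr[1L] + f * nvec[1L]; cols <- ctr[2L] + f * nvec[2L]
    y <- smooth_gauss(bilinear_sample(m, rows, cols), 2 * sigma_px)
    cidx <- (nsamp + 1L) %/% 2L
    # background from the probe tails, band minimum from the whole probe
    tail_n <- max(4L, floor(nsamp * 0.1))
    bg <- stats::median(c(y[seq_len(tail_n)], y[(nsamp - tail_n + 1L):nsamp]))
    dk <- min(y)
    if (bg - dk < 0.05) next
    level <- (bg + dk) / 2
    if (y[cidx] >= level) next  # probe centre not on the dark band
    a <- cidx; while (a > 1L && y[a - 1L] < level) a <- a - 1L
    b <- cidx; while (b < nsamp && y[b + 1L] < level) b <- b + 1L
    if (a == 1L || b == nsamp) next  # band truncated by the probe
    fa <- (y[a - 1L] - level) / (y[a - 1L] - y[a])
    fb <- (y[b] - level) / (y[b] - y[b + 1L])
    step_px <- f[2L] - f[1L]
    # crossings sit at (a - 1 + fa) and (b + fb) in sample units
    widths[i] <- ((b - a + 1) + fb - fa) * step_px * image$pixel_size
  }
  ok <- !is.na(widths)
  if (mean(ok) < 0.5)
    stop(sprintf("bundle thickness failed: %d of %d probes dropped",
                 sum(!ok), n_probes))
  structure(mean(widths[ok]), widths_nm = widths[ok])
}

#' D-band periodicity along a fibril axis
#'
#' Samples intensity along the axis polyline at half-pixel steps, removes a
#' linear trend, and reads the period from the autocorrelation: the lag of
#' the first prominent positive peak, refined by parabolic interpolation
#' and by dividing the highest consistent peak multiple. The result is
#' cross-checked against the dominant periodogram peak; disagreement beyond
#' 10\% flags the estimate as low confidence.
#'
#' @param image a `calibrated_image` (TEM).
#' @param fibril_axis a [polyline()] along one fibril.
#' @param min_periods minimum number of periods the profile must cover
#'   (default 5).
#' @param prominence_floor minimum autocorrelation height for a peak
#'   (default 0.1).
#' @return Period in nm, with attributes `low_confidence` (logical) and
#'   `spectral_period_nm`.
#' @export
d_band_period <- function(image, fibril_axis, min_periods = 5,
                          prominence_floor = 0.1) {
  if (!inherits(fibril_axis, "polyline")) fibril_axis <- polyline(fibril_axis)
  rs <- resample_polyline(fibril_axis, 0.5)
  y <- bilinear_sample(image, rs$points[, 1L], rs$points[, 2L])
  n <- length(y)
  step_nm <- rs$step * image$pixel_size
  x <- seq_len(n)
  y <- stats::residuals(stats::lm.fit(cbind(1, x), y))
  if (stats::sd(y) < 1e-9)
    stop("constant axial profile: no periodicity")
  lag_max <- floor(n / 2)
  ac <- as.numeric(stats::acf(y, lag.max = lag_max, plot = FALSE,
                              demean = TRUE)$acf)[-1L]  # lags 1..lag_max
  # sub-pixel sampling correlates the noise over neighbouring samples, so
  # the fundamental is the first prominent peak beyond the first zero
  # crossing of the autocorrelation, not just beyond lag 1
  zc <- which(ac < 0)
  if (length(zc) == 0L)
    stop("no autocorrelation zero crossing: no detectable periodicity")
  peaks <- which(diff(sign(diff(ac))) == -2) + 1L
  peaks <- peaks[ac[peaks] > prominence_floor & peaks > zc[1L]]
  if (length(peaks) == 0L)
    stop("no autocorrelation peak above the prominence floor: ",
         "no detectable periodicity")
  refine <- function(l) {
    if (l <= 1L || l >= lag_max) return(as.numeric(l))
    a <- ac[l - 1L]; b <- ac[l]; c <- ac[l + 1L]
    den <- a - 2 * b + c
    if (den >= 0) return(as.numeric(l))
    l + 0.5 * (a - c) / den
  }
  l1 <- refine(peaks[1L])
  # use the highest peak multiple consistent with the fundamental
  m_max <- floor((lag_max - 2) / l1)
  per_lag <- l1
  if (m_max >= 2) {
    for (mm in seq(m_max, 2)) {
      target <- mm * l1
      cand <- peaks[abs(peaks - target) < l1 / 4]
      if (length(cand)) {
        per_lag <- refine(cand[which.max(ac[cand])]) / mm
        break
      }
    }
  }
  period_nm <- per_lag * step_nm
  total_nm <- (n - 1) * step_nm
  if (total_nm < min_periods * period_nm)
    stop(sprintf("profile covers only %.1f periods (< %d required)",
                 total_nm / period_nm, min_periods))
  # spectral cross-check
  pw <- Mod(stats::fft(y))[2:(floor(n / 2) + 1L)]^2
  jbin <- which.max(pw)
  spec_nm <- n * step_nm / jbin
  low_conf <- abs(period_nm - spec_nm) / period_nm > 0.10
  structure(period_nm, low_confidence = low_conf, spectral_period_nm = spec_nm)
}

#' Trace a bundle centerline from a seed point
#'
#' Thresholds the dark phase (Otsu by default), takes the connected
#' component containing the seed, and follows its ridge column by column:
#' the centerline row in each column is the darkness-weighted centroid of
#' the component's pixels. Works for bundles oriented within ~45 degrees of
#' the image x-axis, which covers the synthetic fields; strongly vertical
#' or branching structures are out of scope.
#'
#' @param image a `calibrated_image` (TEM).
#' @param seed_point `(row, col)` on the dark bundle.
#' @param threshold optional gray level; defaults to Otsu on the image.
#' @param min_cols minimum number of columns the component must span.
#' @return A [polyline()] of `(row, col)` centerline points ordered by
#'   column.
#' @export
trace_centerline <- function(image, seed_point, threshold = NULL,
                             min_cols = 10L) {
  m <- image$intensities
  if (is.null(threshold))
    threshold <- EBImage::otsu(matrix(as.numeric(m), ncol = 1L),
                               range = c(0, 1), levels = 256L)
  sp <- round(seed_point)
  if (sp[1L] < 1 || sp[1L] > nrow(m) || sp[2L] < 1 || sp[2L] > ncol(m))
    stop("seed point outside the image")
  # tolerate single noise-flipped pixels: accept the darkest pixel of a
  # small neighbourhood, fail only if the whole patch is bright
  rr <- max(1L, sp[1L] - 2L):min(nrow(m), sp[1L] + 2L)
  cc <- max(1L, sp[2L] - 2L):min(ncol(m), sp[2L] + 2L)
  patch <- m[rr, cc, drop = FALSE]
  if (min(patch) >= threshold)
    stop("seed point lies on bright background, not on a dark bundle")
  w <- which(patch == min(patch), arr.ind = TRUE)[1L, ]
  sp <- c(rr[w[1L]], cc[w[2L]])
  dark <- m < threshold
  lab <- EBImage::bwlabel(dark)
  id <- lab[sp[1L], sp[2L]]
  comp <- lab == id
  # unweighted membership centroid per column: immune to the axial D-band
  # intensity modulation, which would bias a darkness-weighted centroid
  colsum <- colSums(comp)
  cols <- which(colsum > 0)
  if (length(cols) < min_cols)
    stop("traced component spans too few columns")
  rows <- colSums(matrix(seq_len(nrow(m)), nrow(m), ncol(m)) * comp)[cols] /
    colsum[cols]
  # light smoothing removes pixel-quantization jitter without attenuating
  # centerline undulations (sigma << any plausible path wavelength)
  rows <- smooth_gauss(rows, 2)
  polyline(cbind(rows, cols))
}
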