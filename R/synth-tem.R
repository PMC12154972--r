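#' Parameters for a synthetic TEM collagen-bundle field
#'
#' Describes a bundle of parallel collagen fibrils following a sinusoidal
#' centerline. Fibrils are rendered as dark bands of controlled diameter
#' separated by gaps of controlled edge-to-edge width, each modulated along
#' its axis with the axial D-band period. Two acquisition regimes are
#' covered by the pixel size: a bundle scale (~8 nm/px, where the bundle
#' reads as one dark band) and a fibril scale (~1.5 nm/px, where individual
#' fibrils and gaps resolve).
#'
#' @param image_size integer `(rows, cols)`.
#' @param pixel_size_nm nanometres per pixel (> 0).
#' @param fibril_diameter_nm fibril diameter (>= 3 pixels).
#' @param interfibrillar_gap_nm edge-to-edge gap between neighbours (> 0).
#' @param n_fibrils number of fibrils in the bundle (>= 1).
#' @param d_period_nm axial D-band period (>= 4 pixels, Nyquist margin).
#' @param d_band_contrast fractional intensity modulation in \[0, 1\].
#' @param centerline_amplitude_nm,centerline_wavelength_nm sinusoidal bundle
#'   path `y = A sin(2 pi x / lambda + phase)`; the wavelength must exceed
#'   twice the amplitude and the bundle must fit the canvas.
#' @param fibril_intensity,gap_intensity,background_intensity gray levels of
#'   the fibril interior, the intra-bundle gaps and the surround. At the
#'   bundle scale interfibrillar gaps are unresolved, which is emulated by a
#'   `gap_intensity` below the half-depth level; at the fibril scale it
#'   equals the background so gaps read bright.
#' @param noise_sd additive Gaussian noise SD (>= 0).
#' @param seed integer seed (also draws the centerline and D-band phases).
#' @return A validated `synth_tem_params` list.
#' @export
synth_tem_params <- function(image_size = c(256L, 384L),
                             pixel_size_nm = 1.5,
                             fibril_diameter_nm = 80,
                             interfibrillar_gap_nm = 20,
                             n_fibrils = 3L,
                             d_period_nm = 64,
                             d_band_contrast = 0.35,
                             centerline_amplitude_nm = 0,
                             centerline_wavelength_nm = 2400,
                             fibril_intensity = 0.25,
                             gap_intensity = 0.85,
                             background_intensity = 0.85,
                             noise_sd = 0.05,
                             seed = 1L) {
  p <- list(image_size = as.integer(image_size), pixel_size_nm = pixel_size_nm,
            fibril_diameter_nm = fibril_diameter_nm,
            interfibrillar_gap_nm = interfibrillar_gap_nm,
            n_fibrils = as.integer(n_fibrils), d_period_nm = d_period_nm,
            d_band_contrast = d_band_contrast,
            centerline_amplitude_nm = centerline_amplitude_nm,
            centerline_wavelength_nm = centerline_wavelength_nm,
            fibril_intensity = fibril_intensity, gap_intensity = gap_intensity,
            background_intensity = background_intensity,
            noise_sd = noise_sd, seed = as.integer(seed))
  validate_tem_params(p)
  class(p) <- "synth_tem_params"
  p
}

#' Total bundle thickness implied by TEM parameters
#' @param params a `synth_tem_params` object.
#' @return Envelope thickness in nm: `n * diameter + (n - 1) * gap`.
#' @export
bundle_thickness_nm <- function(params) {
  params$n_fibrils * params$fibril_diameter_nm +
    (params$n_fibrils - 1L) * params$interfibrillar_gap_nm
}

validate_tem_params <- function(p) {
  stopifnot(length(p$image_size) == 2L, all(p$image_size >= 16L),
            p$pixel_size_nm > 0, p$fibril_diameter_nm > 0,
            p$interfibrillar_gap_nm > 0, p$n_fibrils >= 1L,
            p$d_period_nm > 0, p$d_band_contrast >= 0, p$d_band_contrast <= 1,
            p$centerline_amplitude_nm >= 0, p$centerline_wavelength_nm > 0,
            p$noise_sd >= 0)
  if (p$fibril_diameter_nm < 3 * p$pixel_size_nm)
    stop("fibril_diameter_nm must be at least 3 pixels")
  if (p$d_period_nm < 4 * p$pixel_size_nm)
    stop("d_period_nm must be at least 4 pixels (Nyquist margin)")
  if (!(p$centerline_wavelength_nm > 2 * p$centerline_amplitude_nm))
    stop("centerline_wavelength_nm must exceed twice the amplitude")
  half <- bundle_thickness_nm(p) / 2
  rows_nm <- (p$image_size[1L] - 1L) * p$pixel_size_nm
  margin <- 4 * p$pixel_size_nm
  if (p$centerline_amplitude_nm + half + margin > rows_nm / 2)
    stop(sprintf(paste0("bundle geometry exceeds the canvas: amplitude + half",
                        "-thickness = %.0f nm but only %.0f nm of half-height",
                        " is available"),
                 p$centerline_amplitude_nm + half, rows_nm / 2 - margin))
  if (p$centerline_amplitude_nm > 0) {
    # offset curves must not self-intersect: keep the bundle half-width
    # well inside the minimum radius of curvature of the centerline
    k <- 2 * pi / p$centerline_wavelength_nm
    rmin <- 1 / (p$centerline_amplitude_nm * k^2)
    if (half > 0.8 * rmin)
      stop(sprintf(paste0("bundle too thick for the centerline curvature ",
                          "(half-width %.0f nm > 0.8 x min curvature radius ",
                          "%.0f nm)"), half, rmin))
  }
  invisible(p)
}

#' Linearity index of a sinusoidal path
#'
#' Arc length over one period of `y = A sin(2 pi x / lambda)` divided by the
#' period, by adaptive quadrature.
#'
#' @param amplitude_nm,wavelength_nm path parameters.
#' @return Dimensionless linearity (tortuosity) index, >= 1.
#' @export
sinusoid_linearity <- function(amplitude_nm, wavelength_nm) {
  if (amplitude_nm == 0) return(1)
  k <- 2 * pi / wavelength_nm
  f <- function(x) sqrt(1 + (amplitude_nm * k)^2 * cos(k * x)^2)
  stats::integrate(f, 0, wavelength_nm, rel.tol = 1e-10)$value / wavelength_nm
}

#' Amplitude giving a target linearity index
#'
#' Inverts [sinusoid_linearity()] for a fixed wavelength; used to design
#' cohorts with prescribed bundle tortuosity.
#'
#' @param target_index linearity index >= 1.
#' @param wavelength_nm path wavelength.
#' @return Amplitude in nm.
#' @export
amplitude_for_linearity <- function(target_index, wavelength_nm) {
  stopifnot(target_index >= 1)
  if (target_index == 1) return(0)
  stats::uniroot(function(a) sinusoid_linearity(a, wavelength_nm) - target_index,
                 lower = 0, upper = 0.49 * wavelength_nm, tol = 1e-9)$root
}

# signed perpendicular offset u and axial arc-length coordinate s of every
# pixel relative to the sinusoid y(x) = y0 + A sin(kx + phase), solved by
# vectorized Newton iteration on the nearest-point condition
sinusoid_frame <- function(nr, nc, px, y0, A, k, phase) {
  x <- matrix((seq_len(nc) - 1) * px, nr, nc, byrow = TRUE)
  y <- matrix((seq_len(nr) - 1) * px, nr, nc)
  if (A == 0) {
    return(list(u = y - y0, s = x))
  }
  t <- x
  for (i in 1:7) {
    sn <- sin(k * t + phase); cs <- cos(k * t + phase)
    yc <- y0 + A * sn
    yp <- A * k * cs
    f1 <- (t - x) + (yc - y) * yp
    f2 <- 1 + yp^2 - (yc - y) * A * k^2 * sn
    t <- t - f1 / pmax(f2, 0.25)
  }
  sn <- sin(k * t + phase); cs <- cos(k * t + phase)
  yp <- A * k * cs
  den <- sqrt(1 + yp^2)
  u <- ((y - (y0 + A * sn)) - (x - t) * yp) / den
  # arc length s(t) by cumulative trapezoid on a fine grid
  tg <- seq(min(t) - px, max(t) + px, by = px / 2)
  ypg <- A * k * cos(k * tg + phase)
  sg <- c(0, cumsum((sqrt(1 + ypg[-1]^2) + sqrt(1 + ypg[-length(ypg)]^2)) / 2 *
                      diff(tg)))
  s <- matrix(stats::approx(tg, sg, xout = as.vector(t))$y, nr, nc)
  list(u = u, s = s)
}

#' Generate a synthetic TEM field of a wavy collagen bundle
#'
#' Renders `n_fibrils` parallel dark bands following offset curves of a
#' sinusoidal centerline, with bright interfibrillar gaps and axial D-band
#' intensity modulation, plus exact geometric ground truth. Output is
#' deterministic per seed.
#'
#' @param params a [synth_tem_params()] object.
#' @return A list with elements `image` (a `calibrated_image`) and `truth`:
#'   `centerline` (polyline, pixel coords), `fibril_axes` (list of
#'   polylines), `true_linearity_index`, `true_bundle_thickness_nm`,
#'   `true_fibril_diameters_nm`, `true_gaps_nm`, `true_d_period_nm`.
#' @export
generate_tem_bundle <- function(params) {
  validate_tem_params(params)
  nr <- params$image_size[1L]; nc <- params$image_size[2L]
  px <- params$pixel_size_nm
  A <- params$centerline_amplitude_nm
  k <- 2 * pi / params$centerline_wavelength_nm
  n <- params$n_fibrils
  d <- params$fibril_diameter_nm; g <- params$interfibrillar_gap_nm
  y0 <- (nr - 1) / 2 * px
  set.seed(params$seed)
  phase <- stats::runif(1, 0, 2 * pi)
  band_phase <- stats::runif(n, 0, 2 * pi)

  fr <- sinusoid_frame(nr, nc, px, y0, A, k, phase)
  offsets <- (seq_len(n) - (n + 1) / 2) * (d + g)
  edges <- as.vector(rbind(offsets - d / 2, offsets + d / 2))
  idx <- findInterval(fr$u, edges)
  infib <- idx %% 2L == 1L
  half <- bundle_thickness_nm(params) / 2
  inbundle <- abs(fr$u) <= half

  img <- matrix(params$background_intensity, nr, nc)
  img[inbundle] <- params$gap_intensity
  fib_id <- (idx[infib] + 1L) %/% 2L
  img[infib] <- params$fibril_intensity *
    (1 + params$d_band_contrast *
       cos(2 * pi * fr$s[infib] / params$d_period_nm + band_phase[fib_id]))
  if (params$noise_sd > 0)
    img <- img + stats::rnorm(nr * nc, sd = params$noise_sd)
  img <- quantize16(img)

  # ground-truth geometry in pixel coordinates, one vertex per column
  xs <- (seq_len(nc) - 1) * px
  yc <- y0 + A * sin(k * xs + phase)
  center <- polyline(cbind(yc / px + 1, seq_len(nc)))
  ypx <- A * k * cos(k * xs + phase)
  den <- sqrt(1 + ypx^2)
  axes <- lapply(offsets, function(o)
    polyline(cbind((yc + o / den) / px + 1, (xs - o * ypx / den) / px + 1)))

  # arc length / chord over the rendered span, by dense trapezoid rule
  xf <- seq(0, (nc - 1) * px, length.out = 50L * nc)
  ypf <- A * k * cos(k * xf + phase)
  arc <- sum((sqrt(1 + ypf[-1]^2) + sqrt(1 + ypf[-length(xf)]^2)) / 2 * diff(xf))
  chord <- sqrt((xf[length(xf)] - xf[1])^2 + (yc[nc] - yc[1])^2)

  list(image = calibrated_image(img, px, "TEM"),
       truth = list(centerline = center,
                    fibril_axes = axes,
                    centerline_phase = phase,
                    true_linearity_index = arc / chord,
                    true_bundle_thickness_nm = bundle_thickness_nm(params),
                    true_fibril_diameters_nm = rep(d, n),
                    true_gaps_nm = rep(g, max(n - 1L, 0L)),
                    true_d_period_nm = params$d_period_nm))
}
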