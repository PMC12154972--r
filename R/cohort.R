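#' Experiment design for a synthetic cohort
#'
#' Describes the full 2 conditions (CT, HA) x 2 timepoints (24 h, 48 h) x
#' 2 dermis layers (papillary, reticular) x 2 replicates design, with
#' per-group generator parameters for three image kinds: light-microscopy
#' sections (amorphous fraction), bundle-scale TEM fields (thickness,
#' linearity) and fibril-scale TEM fields (fibril diameter, interfibrillar
#' distance, D-band period).
#'
#' Layer baselines follow the control-tissue regimes: papillary sections
#' are compact (amorphous fraction 0.135, the middle of the 11-16\% range)
#' with thinner bundles (8 fibrils), reticular sections are loose
#' (fraction 0.255, middle of 23-28\%) with thicker bundles (12 fibrils).
#'
#' @param n_lm LM images per group (default 40, 20 per replicate).
#' @param n_tem bundle- and fibril-scale TEM images per group (default 40).
#' @param n_dband D-band measurements per group (default 100, 50 per
#'   replicate, up to `n_fibrils` per fibril-scale image).
#' @param lm_image_size,tem_image_size canvas sizes in pixels.
#' @param base_linearity bundle linearity index shared by all groups unless
#'   overridden.
#' @param overrides named list: `group key -> list of parameter overrides`.
#'   Group keys look like `"HA_24h_reticular"`; recognised overrides are
#'   `lm_target`, `thickness_scale` (scales fibril diameter and gap in the
#'   bundle regime jointly), `linearity_index`, `fibril_diameter_nm`,
#'   `gap_nm`, `d_period_nm`.
#' @return A `cohort_design` list.
#' @export
cohort_design <- function(n_lm = 40L, n_tem = 40L, n_dband = 100L,
                          lm_image_size = c(256L, 256L),
                          tem_image_size = c(256L, 384L),
                          base_linearity = 1.08,
                          overrides = list()) {
  base <- list(
    lm = list(image_size = as.integer(lm_image_size), pixel_size_um = 0.74,
              blob_length_scale_um = 6, stained_intensity_mean = 0.3,
              unstained_intensity_mean = 0.8, noise_sd = 0.05,
              lm_target = list(papillary = 0.135, reticular = 0.255),
              # per-image target fraction is drawn uniformly in
              # mean +/- halfwidth: sections differ from field to field
              lm_target_halfwidth = 0.025),
    bundle = list(image_size = as.integer(tem_image_size), pixel_size_nm = 8,
                  fibril_diameter_nm = 80, interfibrillar_gap_nm = 20,
                  n_fibrils = list(papillary = 8L, reticular = 10L),
                  d_period_nm = 64, d_band_contrast = 0.35,
                  centerline_wavelength_nm = 3200,
                  linearity_index = base_linearity,
                  # between-bundle heterogeneity (biological spread)
                  size_cv = 0.06, linearity_sd = 0.015,
                  fibril_intensity = 0.25, gap_intensity = 0.45,
                  background_intensity = 0.85, noise_sd = 0.05),
    fibril = list(image_size = as.integer(tem_image_size), pixel_size_nm = 1.5,
                  fibril_diameter_nm = 80, interfibrillar_gap_nm = 20,
                  n_fibrils = 3L, d_period_nm = 64, d_band_contrast = 0.35,
                  centerline_wavelength_nm = 2400,
                  # between-fibril heterogeneity (biological spread)
                  diameter_cv = 0.06, gap_cv = 0.12, d_period_sd_nm = 1.2,
                  fibril_intensity = 0.25, gap_intensity = 0.85,
                  background_intensity = 0.85, noise_sd = 0.05))
  structure(list(base = base, overrides = overrides,
                 n = list(lm = as.integer(n_lm), tem = as.integer(n_tem),
                          dband = as.integer(n_dband))),
            class = "cohort_design")
}

#' Null design: identical parameters in every group
#' @inheritParams cohort_design
#' @return A `cohort_design` with no group differences.
#' @export
default_cohort_design <- function(n_lm = 40L, n_tem = 40L, n_dband = 100L) {
  cohort_design(n_lm = n_lm, n_tem = n_tem, n_dband = n_dband)
}

#' Design encoding the HA reticular-24h effects
#'
#' Relative to a control reticular baseline (amorphous fraction 0.23), the
#' HA-treated reticular group at 24 h carries: amorphous fraction 0.28
#' (+5 percentage points), bundle thickness -10\%, bundle linearity +5\%,
#' fibril diameter +10\%, interfibrillar distance -20\%, D-band period
#' unchanged.
#'
#' @inheritParams cohort_design
#' @return A `cohort_design`.
#' @export
ha_effect_design <- function(n_lm = 40L, n_tem = 40L, n_dband = 100L) {
  d <- cohort_design(n_lm = n_lm, n_tem = n_tem, n_dband = n_dband)
  d$base$lm$lm_target$reticular <- 0.23
  d$overrides <- list(
    HA_24h_reticular = list(lm_target = 0.28,
                            thickness_scale = 0.9,
                            linearity_index = 1.08 * 1.05,
                            fibril_diameter_nm = 88,
                            gap_nm = 16))
  d
}

cohort_groups <- function() {
  g <- expand.grid(condition = c("CT", "HA"), timepoint = c(24L, 48L),
                   layer = c("papillary", "reticular"),
                   stringsAsFactors = FALSE)
  g$key <- group_key(g$condition, g$timepoint, g$layer)
  g
}

group_override <- function(design, key, field, default) {
  ov <- design$overrides[[key]]
  if (!is.null(ov) && !is.null(ov[[field]])) ov[[field]] else default
}

# normal draw truncated to +/- 2.5 sd (keeps per-image truths physical)
rnorm_trunc <- function(mean, sd) {
  x <- stats::rnorm(1, mean, sd)
  min(max(x, mean - 2.5 * sd), mean + 2.5 * sd)
}

# generator params for one image of a given kind in a given group.
# The image seed drives both the per-image biological heterogeneity draws
# and (through a derived sub-seed) the rendering noise.
group_image_params <- function(design, key, layer, kind, seed) {
  set.seed(seed)
  if (kind == "lm") {
    b <- design$base$lm
    tgt <- group_override(design, key, "lm_target", b$lm_target[[layer]])
    tgt <- tgt + stats::runif(1, -b$lm_target_halfwidth, b$lm_target_halfwidth)
    render_seed <- sample.int(2147483646L, 1L)
    return(synth_histology_params(
      image_size = b$image_size, pixel_size_um = b$pixel_size_um,
      target_amorphous_fraction = min(max(tgt, 0), 1),
      blob_length_scale_um = b$blob_length_scale_um,
      stained_intensity_mean = b$stained_intensity_mean,
      unstained_intensity_mean = b$unstained_intensity_mean,
      noise_sd = b$noise_sd, seed = render_seed))
  }
  if (kind == "tem_bundle") {
    b <- design$base$bundle
    scl <- group_override(design, key, "thickness_scale", 1) *
      rnorm_trunc(1, b$size_cv)
    li <- group_override(design, key, "linearity_index", b$linearity_index)
    li <- max(1, rnorm_trunc(li, b$linearity_sd))
    render_seed <- sample.int(2147483646L, 1L)
    amp <- amplitude_for_linearity(li, b$centerline_wavelength_nm)
    # cap the amplitude at the geometric feasibility limit of the drawn
    # bundle size (offset-curve curvature bound and canvas height); the
    # cap only binds in the extreme tail of the joint draws and perturbs
    # the realized linearity by well under a per mille
    nf <- b$n_fibrils[[layer]]
    half <- (nf * b$fibril_diameter_nm + (nf - 1) * b$interfibrillar_gap_nm) *
      scl / 2
    k2 <- (2 * pi / b$centerline_wavelength_nm)^2
    a_curv <- 0.999 * 0.8 / (half * k2)
    a_canvas <- (b$image_size[1L] - 1L) * b$pixel_size_nm / 2 - half -
      4.001 * b$pixel_size_nm
    amp <- min(amp, a_curv, a_canvas)
    return(synth_tem_params(
      image_size = b$image_size, pixel_size_nm = b$pixel_size_nm,
      fibril_diameter_nm = b$fibril_diameter_nm * scl,
      interfibrillar_gap_nm = b$interfibrillar_gap_nm * scl,
      n_fibrils = b$n_fibrils[[layer]], d_period_nm = b$d_period_nm,
      d_band_contrast = b$d_band_contrast,
      centerline_amplitude_nm = amp,
      centerline_wavelength_nm = b$centerline_wavelength_nm,
      fibril_intensity = b$fibril_intensity, gap_intensity = b$gap_intensity,
      background_intensity = b$background_intensity,
      noise_sd = b$noise_sd, seed = render_seed))
  }
  b <- design$base$fibril
  d0 <- group_override(design, key, "fibril_diameter_nm", b$fibril_diameter_nm)
  g0 <- group_override(design, key, "gap_nm", b$interfibrillar_gap_nm)
  p0 <- group_override(design, key, "d_period_nm", b$d_period_nm)
  d0 <- max(3 * b$pixel_size_nm, rnorm_trunc(d0, b$diameter_cv * d0))
  g0 <- max(2 * b$pixel_size_nm, rnorm_trunc(g0, b$gap_cv * g0))
  p0 <- max(4 * b$pixel_size_nm, rnorm_trunc(p0, b$d_period_sd_nm))
  render_seed <- sample.int(2147483646L, 1L)
  return(synth_tem_params(
    image_size = b$image_size, pixel_size_nm = b$pixel_size_nm,
    fibril_diameter_nm = d0, interfibrillar_gap_nm = g0,
    n_fibrils = b$n_fibrils, d_period_nm = p0,
    d_band_contrast = b$d_band_contrast,
    centerline_amplitude_nm = 0,
    centerline_wavelength_nm = b$centerline_wavelength_nm,
    fibril_intensity = b$fibril_intensity, gap_intensity = b$gap_intensity,
    background_intensity = b$background_intensity,
    noise_sd = b$noise_sd, seed = render_seed))
}

# the fixed enumeration of every image in a cohort; per-image seeds are
# drawn once from the master seed so the manifest is fully reproducible
cohort_schedule <- function(design, master_seed) {
  g <- cohort_groups()
  rows <- list()
  for (i in seq_len(nrow(g))) {
    for (kind in c("lm", "tem_bundle", "tem_fibril")) {
      n <- if (kind == "lm") design$n$lm else design$n$tem
      if (n == 0L) next
      rep_of <- rep(1:2, each = ceiling(n / 2))[seq_len(n)]
      rows[[length(rows) + 1L]] <- data.frame(
        kind = kind, condition = g$condition[i], timepoint = g$timepoint[i],
        layer = g$layer[i], replicate = rep_of, key = g$key[i],
        stringsAsFactors = FALSE)
    }
  }
  sched <- do.call(rbind, rows)
  sched$index <- seq_len(nrow(sched))
  set.seed(master_seed)
  sched$seed <- sample.int(2147483646L, nrow(sched))
  sched
}

# generate one scheduled image with its sidecar metadata
generate_scheduled_image <- function(design, sched_row) {
  params <- group_image_params(design, sched_row$key, sched_row$layer,
                               sched_row$kind, sched_row$seed)
  if (sched_row$kind == "lm") {
    out <- generate_he_section(params)
    sidecar <- list(kind = "lm", modality = "LM",
                    pixel_size = params$pixel_size_um,
                    seed = params$seed,
                    annotations = list(),
                    truth = list(amorphous_fraction = out$truth$amorphous_fraction,
                                 amorphous_mask_rle = rle_encode(out$truth$amorphous_mask)))
  } else {
    out <- generate_tem_bundle(params)
    nr <- params$image_size[1L]; nc <- params$image_size[2L]
    mid <- unclass(out$truth$centerline)[nc %/% 2L, ]
    ann <- list(seed_point = as.numeric(mid))
    if (sched_row$kind == "tem_fibril") {
      ann$transect <- rbind(c(2, nc / 2), c(nr - 1, nc / 2))
      # named list, so JSON keeps it as an object of per-axis point arrays
      ax <- lapply(out$truth$fibril_axes, unclass)
      names(ax) <- sprintf("axis_%d", seq_along(ax))
      ann$fibril_axes <- ax
    }
    sidecar <- list(kind = sched_row$kind, modality = "TEM",
                    pixel_size = params$pixel_size_nm,
                    seed = params$seed,
                    annotations = ann,
                    truth = list(
                      true_linearity_index = out$truth$true_linearity_index,
                      true_bundle_thickness_nm = out$truth$true_bundle_thickness_nm,
                      true_fibril_diameters_nm = out$truth$true_fibril_diameters_nm,
                      true_gaps_nm = out$truth$true_gaps_nm,
                      true_d_period_nm = out$truth$true_d_period_nm))
  }
  list(image = out$image, sidecar = sidecar, truth = out$truth)
}

# run-length encoding of a logical mask (column-major), for JSON sidecars
rle_encode <- function(mask) {
  r <- rle(as.vector(mask))
  list(dim = dim(mask), first = r$values[1L], lengths = r$lengths)
}

rle_decode <- function(enc) {
  n <- length(enc$lengths)
  vals <- rep(c(enc$first, !enc$first), length.out = n)
  matrix(inverse.rle(list(lengths = enc$lengths, values = vals)),
         enc$dim[1L], enc$dim[2L])
}

#' Generate a synthetic cohort on disk
#'
#' Writes every scheduled image as a 16-bit grayscale TIFF with a JSON
#' sidecar (annotations plus generator ground truth) and a manifest CSV
#' listing image paths, group tags and per-image seeds. Identical design
#' and seed reproduce the cohort byte for byte.
#'
#' @param design a [cohort_design()].
#' @param seed master integer seed.
#' @param out_dir output directory (created if missing).
#' @return The manifest data frame, invisibly; also written as
#'   `manifest.csv` in `out_dir`.
#' @export
generate_cohort <- function(design, seed, out_dir) {
  stopifnot(inherits(design, "cohort_design"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sched <- cohort_schedule(design, seed)
  paths <- character(nrow(sched))
  for (i in seq_len(nrow(sched))) {
    gen <- generate_scheduled_image(design, sched[i, ])
    stem <- sprintf("img_%04d_%s_%s", sched$index[i], sched$kind[i],
                    sched$key[i])
    paths[i] <- file.path(out_dir, paste0(stem, ".tiff"))
    write_image(gen$image, paths[i])
    jsonlite::write_json(gen$sidecar, file.path(out_dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = FALSE)
  }
  manifest <- data.frame(image_path = basename(paths), kind = sched$kind,
                         condition = sched$condition,
                         timepoint = sched$timepoint, layer = sched$layer,
                         replicate = sched$replicate, seed = sched$seed,
                         pixel_size = vapply(seq_len(nrow(sched)), function(i)
                           if (sched$kind[i] == "lm") design$base$lm$pixel_size_um
                           else if (sched$kind[i] == "tem_bundle")
                             design$base$bundle$pixel_size_nm
                           else design$base$fibril$pixel_size_nm, numeric(1)),
                         master_seed = seed)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
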