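test_that("H&E generator hits target fractions and degenerate limits", {
  # degenerate fractions
  p0 <- synth_histology_params(target_amorphous_fraction = 0, seed = 3)
  out0 <- generate_he_section(p0)
  expect_false(any(out0$truth$amorphous_mask))
  expect_lt(abs(mean(out0$image$intensities) - p0$stained_intensity_mean), 0.01)
  p1 <- synth_histology_params(target_amorphous_fraction = 1, seed = 3)
  expect_true(all(generate_he_section(p1)$truth$amorphous_mask))

  # realized fraction tracks the target across the supported range
  for (tgt in c(0.05, 0.11, 0.16, 0.23, 0.28, 0.4, 0.5)) {
    out <- generate_he_section(
      synth_histology_params(target_amorphous_fraction = tgt, seed = 11))
    expect_lt(abs(mean(out$truth$amorphous_mask) - tgt), 0.01)
  }

  # the 0.25 example: mask pixel fraction in [0.24, 0.26]
  out <- generate_he_section(
    synth_histology_params(target_amorphous_fraction = 0.25, seed = 1))
  frac <- sum(out$truth$amorphous_mask) / length(out$truth$amorphous_mask)
  expect_gte(frac, 0.24); expect_lte(frac, 0.26)
})

test_that("H&E generator is deterministic per seed and validates inputs", {
  p <- synth_histology_params(target_amorphous_fraction = 0.2, seed = 42)
  a <- generate_he_section(p); b <- generate_he_section(p)
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(a$truth$amorphous_mask, b$truth$amorphous_mask)
  c <- generate_he_section(synth_histology_params(
    target_amorphous_fraction = 0.2, seed = 43))
  expect_false(identical(a$image$intensities, c$image$intensities))

  expect_error(synth_histology_params(target_amorphous_fraction = 1.2),
               "\\[0, 1\\]")
  expect_error(synth_histology_params(stained_intensity_mean = 0.7,
                                      unstained_intensity_mean = 0.75,
                                      noise_sd = 0.05),
               "not separable")
  expect_error(generate_he_section(
    synth_histology_params(image_size = c(32L, 32L),
                           blob_length_scale_um = 50)),
    "achievable range")
})

test_that("TEM ground-truth linearity matches arc-length quadrature", {
  # straight path
  p <- synth_tem_params(centerline_amplitude_nm = 0, seed = 1)
  expect_equal(generate_tem_bundle(p)$truth$true_linearity_index, 1,
               tolerance = 1e-9)

  # wavy paths across amplitudes up to lambda/4, checked against
  # independent quadrature of the arc-length integral over the same span
  lam <- 3200
  for (A in c(100, 300, 600, 800)) {
    pp <- synth_tem_params(image_size = c(256L, 384L), pixel_size_nm = 8,
                           n_fibrils = 3L, centerline_amplitude_nm = A,
                           centerline_wavelength_nm = lam, seed = 9)
    tb <- generate_tem_bundle(pp)
    span <- (384 - 1) * 8
    phase <- tb$truth$centerline_phase
    arc <- sinusoid_arc_quadrature(A, lam, span, phase)
    k <- 2 * pi / lam
    dy <- A * sin(k * span + phase) - A * sin(phase)
    chord <- sqrt(span^2 + dy^2)
    expect_equal(tb$truth$true_linearity_index, arc / chord,
                 tolerance = 1e-3)
  }
})

test_that("noiseless TEM axial profile has its spectral peak at the D period", {
  # d_period 60 nm at 2 nm/px: spectral peak at a 30 px period
  p <- synth_tem_params(pixel_size_nm = 2, fibril_diameter_nm = 80,
                        d_period_nm = 60, noise_sd = 0, seed = 4)
  tb <- generate_tem_bundle(p)
  ax <- unclass(tb$truth$fibril_axes[[2]])
  prof <- bilinear_sample(tb$image, ax[, 1], ax[, 2])
  prof <- prof - mean(prof)
  n <- length(prof)
  pw <- Mod(stats::fft(prof))[2:(n %/% 2)]^2
  jbin <- which.max(pw)
  period_px <- n / jbin  # samples are 1 px apart along the straight axis
  expect_lt(abs(period_px - 30), n / jbin - n / (jbin + 1))  # within one bin
  expect_equal(period_px, 30, tolerance = 0.05)
})

test_that("TEM generator is deterministic and rejects impossible geometry", {
  p <- synth_tem_params(seed = 5)
  a <- generate_tem_bundle(p); b <- generate_tem_bundle(p)
  expect_identical(a$image$intensities, b$image$intensities)
  expect_equal(unclass(a$truth$centerline), unclass(b$truth$centerline))

  expect_error(synth_tem_params(n_fibrils = 40L), "exceeds the canvas")
  expect_error(synth_tem_params(fibril_diameter_nm = 3), "at least 3 pixels")
  expect_error(synth_tem_params(d_period_nm = 4), "Nyquist")
  expect_error(synth_tem_params(centerline_amplitude_nm = 300,
                                centerline_wavelength_nm = 500),
               "twice the amplitude")
})

test_that("cohort generation writes a reproducible manifest and sidecars", {
  d <- default_cohort_design(n_lm = 1L, n_tem = 1L, n_dband = 2L)
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  m1 <- generate_cohort(d, seed = 21, out_dir = dir1)
  m2 <- generate_cohort(d, seed = 21, out_dir = dir2)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 8 * 3)  # 8 groups x (1 lm + 1 bundle + 1 fibril)
  # byte-identical rasters and sidecars across the two runs
  for (f in list.files(dir1)) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))),
                     info = f)
  }
  # sidecar ground truth round-trips through JSON
  sc <- jsonlite::fromJSON(
    file.path(dir1, sub("\\.tiff$", ".json", m1$image_path[1])))
  expect_true(is.list(sc$truth))
})

test_that("effect design shifts realized ground-truth fractions by ~5 pp", {
  d <- ha_effect_design(n_lm = 20L, n_tem = 0L)
  sched <- dermometry:::cohort_schedule(d, 31L)
  sched <- sched[sched$kind == "lm" & sched$layer == "reticular" &
                   sched$timepoint == 24, ]
  fr <- vapply(seq_len(nrow(sched)), function(i) {
    g <- dermometry:::generate_scheduled_image(d, sched[i, ])
    g$truth$amorphous_fraction
  }, numeric(1))
  ct <- fr[sched$condition == "CT"]; ha <- fr[sched$condition == "HA"]
  expect_lt(abs((mean(ha) - mean(ct)) - 0.05), 0.015)
})
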