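test_that("linearity index: collinear, semicircle, sinusoid, invariances", {
  expect_equal(linearity_index(polyline(cbind(c(0, 0, 0), c(0, 5, 9)))), 1)

  th <- seq(0, pi, length.out = 1000)
  semi <- polyline(cbind(10 * sin(th), 10 * cos(th)))
  expect_equal(linearity_index(semi), pi / 2, tolerance = 1e-3)

  # sinusoid A = 100 nm, lambda = 1000 nm over one period vs quadrature
  x <- seq(0, 1000, length.out = 2000)
  sine <- polyline(cbind(100 * sin(2 * pi * x / 1000), x))
  expect_equal(linearity_index(sine),
               sinusoid_arc_quadrature(100, 1000, 1000) / 1000,
               tolerance = 1e-3)

  # rotation + translation + uniform scaling leave the index unchanged
  p <- unclass(sine)
  ang <- 0.7; R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2)
  q <- sweep(3 * p %*% R, 2, c(12, -5), "+")
  expect_equal(linearity_index(polyline(q)), linearity_index(sine),
               tolerance = 1e-12)

  expect_error(linearity_index(polyline(cbind(c(0, 1, 0), c(0, 1, 0)))),
               "coincident endpoints")
})

test_that("bundle thickness: straight ribbon, calibration linearity, wavy bundle", {
  rb <- make_ribbon_image(width_px = 20L, pixel_size_nm = 10)
  cl <- polyline(cbind(rep(rb$center_row, 2), c(10, 190)))
  th <- bundle_thickness(rb$image, cl)
  expect_equal(as.numeric(th), 200, tolerance = 10 / 200)  # +/- 1 px

  # same pixel geometry at half the pixel size -> half the thickness
  img5 <- calibrated_image(rb$image$intensities, 5, "TEM")
  expect_equal(as.numeric(bundle_thickness(img5, cl)),
               as.numeric(th) / 2, tolerance = 1e-9)

  # wavy synthetic bundle within 5% of ground truth
  p <- synth_tem_params(image_size = c(256L, 384L), pixel_size_nm = 8,
                        n_fibrils = 10L, gap_intensity = 0.45,
                        centerline_amplitude_nm = 250,
                        centerline_wavelength_nm = 3200, seed = 12)
  tb <- generate_tem_bundle(p)
  thw <- bundle_thickness(tb$image, tb$truth$centerline)
  expect_lt(abs(as.numeric(thw) - tb$truth$true_bundle_thickness_nm) /
              tb$truth$true_bundle_thickness_nm, 0.05)
})

test_that("fibril segmentation: square wave, degenerate input, synthetic bundle", {
  # noiseless square wave: fibrils 50 nm, gaps 10 nm, 1 nm sampling
  one <- c(rep(0.85, 10), rep(0.2, 50))
  prof <- transect_profile(c(rep(one, 4), rep(0.85, 10)), step_nm = 1,
                           pixel_size_nm = 2)
  seg <- measure_fibrils(prof)
  expect_equal(length(seg$diameters_nm), 4L)
  expect_equal(seg$diameters_nm, rep(50, 4), tolerance = 1 / 50)
  expect_equal(seg$gaps_nm, rep(10, 3), tolerance = 1 / 10)

  expect_error(measure_fibrils(transect_profile(rep(0.5, 64), 1)),
               "contrast too low")

  # synthetic fibril-scale bundle: mean diameter within 5% of truth
  p <- synth_tem_params(seed = 33)
  tb <- generate_tem_bundle(p)
  tr <- extract_transect(tb$image, c(2, 192), c(255, 192))
  seg2 <- measure_fibrils(tr)
  expect_equal(length(seg2$diameters_nm), 3L)
  expect_lt(abs(mean(seg2$diameters_nm) -
                  mean(tb$truth$true_fibril_diameters_nm)) /
              mean(tb$truth$true_fibril_diameters_nm), 0.05)
  expect_lt(abs(mean(seg2$gaps_nm) - mean(tb$truth$true_gaps_nm)) /
              mean(tb$truth$true_gaps_nm), 0.10)
})

test_that("D-band period: pure sinusoid, degenerate input, ground truth, invariance", {
  # pure axial sinusoid, period 30 px at 2 nm/px -> 60 nm
  nr <- 64L; nc <- 512L
  m <- matrix(0.5 + 0.2 * sin(2 * pi * (col(matrix(0, nr, nc)) - 1) / 30),
              nr, nc)
  img <- calibrated_image(m, 2, "TEM")
  axis <- polyline(cbind(rep(32, 2), c(1, 512)))
  d <- d_band_period(img, axis)
  expect_equal(as.numeric(d), 60, tolerance = 0.02)
  expect_false(attr(d, "low_confidence"))

  expect_error(d_band_period(calibrated_image(matrix(0.5, 64, 512), 2, "TEM"),
                             axis),
               "no periodicity")

  # synthetic fibril at default noise: within 2% of the 67 nm truth
  p <- synth_tem_params(d_period_nm = 67, seed = 8)
  tb <- generate_tem_bundle(p)
  dd <- d_band_period(tb$image, tb$truth$fibril_axes[[2]])
  expect_equal(as.numeric(dd), 67, tolerance = 0.02)

  # affine intensity rescaling leaves the estimate unchanged
  img2 <- calibrated_image(0.5 * tb$image$intensities + 0.2,
                           tb$image$pixel_size, "TEM")
  dd2 <- d_band_period(img2, tb$truth$fibril_axes[[2]])
  expect_equal(as.numeric(dd2), as.numeric(dd), tolerance = 1e-6)

  # profile must cover at least 5 periods
  short_axis <- polyline(cbind(rep(32, 2), c(1, 100)))
  expect_error(d_band_period(img, short_axis, min_periods = 5), "periods")
})

test_that("centerline tracing recovers straight and wavy bundles, rejects background seeds", {
  rb <- make_ribbon_image()
  pl <- trace_centerline(rb$image, c(rb$center_row, 100))
  expect_lte(linearity_index(pl), 1.02)

  p <- synth_tem_params(image_size = c(256L, 384L), pixel_size_nm = 8,
                        n_fibrils = 10L, gap_intensity = 0.45,
                        centerline_amplitude_nm = 250,
                        centerline_wavelength_nm = 3200, seed = 19)
  tb <- generate_tem_bundle(p)
  seedpt <- unclass(tb$truth$centerline)[192, ]
  tr <- trace_centerline(tb$image, seedpt)
  expect_lt(abs(linearity_index(tr) - tb$truth$true_linearity_index) /
              tb$truth$true_linearity_index, 0.05)

  expect_error(trace_centerline(rb$image, c(5, 100)), "background")
})

test_that("nm-valued outputs scale linearly with pixel size", {
  p1 <- synth_tem_params(pixel_size_nm = 1.5, seed = 44)
  tb <- generate_tem_bundle(p1)
  tr1 <- extract_transect(tb$image, c(2, 192), c(255, 192))
  img2x <- calibrated_image(tb$image$intensities, 3, "TEM")
  tr2 <- extract_transect(img2x, c(2, 192), c(255, 192))
  s1 <- measure_fibrils(tr1); s2 <- measure_fibrils(tr2)
  expect_equal(s2$diameters_nm, 2 * s1$diameters_nm, tolerance = 1e-9)
  d1 <- d_band_period(tb$image, tb$truth$fibril_axes[[1]])
  d2 <- d_band_period(img2x, tb$truth$fibril_axes[[1]])
  expect_equal(as.numeric(d2), 2 * as.numeric(d1), tolerance = 1e-9)
})
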