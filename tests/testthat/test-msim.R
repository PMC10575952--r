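# Rendering and reconstruction of multifocal-excitation stacks.

test_that("zero photons give an all-zero stack and reconstruction", {
  pat <- build_scan_pattern(4)
  ph <- matrix(1, 32, 32)
  st <- render_msim_stack(ph, pat, 0.15, 0.15, photons = 0, pixel_size = 0.1)
  expect_true(all(st == 0))
  rec <- reconstruct(st, pat, pinhole_radius = 1)
  expect_true(all(rec$image == 0))
})

test_that("summed scan frames approximate uniform illumination on a flat sample", {
  pat <- build_scan_pattern(16)
  ph <- matrix(1, 64, 64)
  st <- render_msim_stack(ph, pat, 0.15, 0.15, photons = 1, pixel_size = 0.1)
  tot <- Reduce(`+`, lapply(seq_len(dim(st)[3]), function(k) st[, , k]))
  interior <- tot[17:48, 17:48]
  expect_lt(stats::sd(interior) / mean(interior), 0.02)
})

test_that("widefield rendering is linear in photons and preserves flatness", {
  ph <- matrix(1, 48, 48)
  a <- render_widefield(ph, 0.15, photons = 100, pixel_size = 0.1)
  b <- render_widefield(ph, 0.15, photons = 300, pixel_size = 0.1)
  expect_equal(3 * a[10:38, 10:38], b[10:38, 10:38], tolerance = 1e-10)
  expect_lt(stats::sd(a[10:38, 10:38]) / mean(a[10:38, 10:38]), 1e-6)
})

test_that("flat phantom reconstructs flat (interior CV below 2%)", {
  pat <- build_scan_pattern(16)
  ph <- matrix(1, 64, 64)
  st <- render_msim_stack(ph, pat, 0.15, 0.15, photons = 1, pixel_size = 0.1)
  for (pin in c(0.5, 1.0)) {
    rec <- reconstruct(st, pat, pinhole_radius = pin)
    interior <- rec$image[33:96, 33:96]
    expect_lt(stats::sd(interior) / mean(interior), 0.02)
  }
})

test_that("reconstruction conserves the post-pinhole photon total", {
  pat <- build_scan_pattern(8)
  ph <- cd_phantom()$density[81:144, 81:144]
  st <- render_msim_stack(ph, pat, 0.15, 0.15, photons = 500, pixel_size = 0.1)
  rec <- reconstruct(st, pat, pinhole_radius = 1)
  expect_equal(sum(rec$image), rec$total_in, tolerance = 1e-6)
})

test_that("stack depth must match the scan pattern", {
  pat <- build_scan_pattern(4)
  st <- array(0, dim = c(32, 32, 5))
  expect_error(reconstruct(st, pat), "depth")
})

test_that("an oversized pinhole triggers a crosstalk warning", {
  pat <- build_scan_pattern(4)
  st <- array(0, dim = c(32, 32, nrow(pat$offsets)))
  expect_warning(reconstruct(st, pat, pinhole_radius = 3), "crosstalk")
})

test_that("pixel reassignment sharpens a point source by ~sqrt(2)", {
  ps <- 0.05; n <- 96; sig <- 0.15  # PSF sigma = 3 px
  ph <- matrix(0, n, n); ph[n / 2 + 1, n / 2 + 1] <- 1
  pat <- build_scan_pattern(16)
  wf <- render_widefield(ph, psf_sigma_em = sig, photons = 1, pixel_size = ps)
  st <- render_msim_stack(ph, pat, sig, sig, photons = 1, pixel_size = ps)
  rec <- reconstruct(st, pat, pinhole_radius = 0.5)
  ctr <- c(n / 2, n / 2) * ps
  fw_wf <- measure_fwhm(wf, ctr, pixel_size = ps, window_um = 0.5)
  fw_ms <- measure_fwhm(rec, ctr, window_um = 0.5)
  expect_true(fw_wf$ok && fw_ms$ok)
  expect_equal(fw_wf$fwhm_um, 2 * sqrt(2 * log(2)) * sig, tolerance = 0.02)
  expect_equal(fw_wf$fwhm_um / fw_ms$fwhm_um, sqrt(2), tolerance = 0.02)
})

test_that("measure_fwhm recovers a known Gaussian width", {
  ps <- 0.05
  xs <- (0:63) * ps
  X <- matrix(xs, 64, 64, byrow = TRUE); Y <- t(X)
  img <- exp(-((X - 1.6)^2 + (Y - 1.6)^2) / (2 * 0.1^2))
  fw <- measure_fwhm(img, c(1.6, 1.6), pixel_size = ps, window_um = 0.5)
  expect_true(fw$ok)
  expect_equal(fw$fwhm_um, 2 * sqrt(2 * log(2)) * 0.1, tolerance = 0.02)  # 0.2355
})

test_that("measure_fwhm flags a featureless image instead of erroring", {
  img <- matrix(1, 32, 32)
  fw <- measure_fwhm(img, c(1.5, 1.5), pixel_size = 0.1, window_um = 0.5)
  expect_false(fw$ok)
  expect_true(is.na(fw$fwhm_um))
})

test_that("illumination flattening removes smooth vignetting", {
  xs <- (0:127) * 0.1
  X <- matrix(xs, 128, 128, byrow = TRUE); Y <- t(X)
  vign <- exp(-((X - 6.4)^2 + (Y - 6.4)^2) / (2 * 20^2))  # gentle fall-off
  flat <- flatten_illumination(vign, pixel_size = 0.1, blur_sigma_um = 2.16)
  interior <- flat[33:96, 33:96]
  expect_true(all(abs(interior - 1) < 0.05))
  # uniform image maps to exactly 1
  u <- flatten_illumination(matrix(5, 64, 64), pixel_size = 0.1)
  expect_equal(u[20:44, 20:44], matrix(1, 25, 25), tolerance = 1e-10,
               ignore_attr = TRUE)
  # a delta on a flat background sticks out above 1
  img <- matrix(1, 64, 64); img[32, 32] <- 10
  fl <- flatten_illumination(img, pixel_size = 0.1)
  expect_gt(fl[32, 32], 1)
})

test_that("density normalization is scale invariant with nuclear mean 1", {
  ph <- cd_phantom()
  a <- normalize_density(ph$density, ph$mask, ph$pixel_size)
  b <- normalize_density(ph$density * 7.3, ph$mask, ph$pixel_size)
  expect_equal(a$norm_intensity, b$norm_intensity, tolerance = 1e-12)
  expect_equal(mean(a$norm_intensity[a$mask]), 1, tolerance = 1e-12)
  # chromatin-dense domain centers sit above the nuclear average
  cl <- density_class_at(ph$cd_centers, a)
  vals <- a$norm_intensity[cbind(
    smtmsim:::px_index(ph$cd_centers[, 2], 0.1),
    smtmsim:::px_index(ph$cd_centers[, 1], 0.1))]
  expect_true(all(vals > 1))
})
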