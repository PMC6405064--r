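test_that("CT number and CCN identities hold", {
  expect_equal(ct_number(0.5, 0.5), 0)       # water
  expect_equal(ct_number(0, 0.5), -1000)     # air / vacuum
  expect_equal(ct_number(1.0, 0.5), 1000)    # linearity
  expect_error(ct_number(1, 0), "positive")

  cal <- scan_calibration(mu_air = 2000, mu_calcite = 30000)
  expect_equal(ccn(30000, cal), 1000)
  expect_equal(ccn(2000, cal), 0)
  expect_error(scan_calibration(10, 10), "degenerate")

  # strictly increasing in the sample argument
  v <- seq(0, 40000, length.out = 11)
  expect_true(all(diff(ccn(v, cal)) > 0))
  expect_true(all(diff(ct_number(v + 1, 0.5)) > 0))
})

test_that("CCN is affine-invariant in the grayscale", {
  with_seed(31, {
    for (i in 1:50) {
      mu_air <- runif(1, 500, 5000)
      mu_cal <- mu_air + runif(1, 5000, 40000)
      v <- runif(20, 0, 45000)
      cal <- scan_calibration(mu_air, mu_cal)
      a <- runif(1, 0.2, 5)
      b <- runif(1, -2000, 2000)
      cal2 <- scan_calibration(a * mu_air + b, a * mu_cal + b)
      expect_equal(ccn(a * v + b, cal2), ccn(v, cal), tolerance = 1e-9)
    }
  })
})

test_that("calibration uses eroded labeled regions and reports counts", {
  dims <- c(40, 40, 12)
  v <- array(0, dim = dims)
  lab <- array(0L, dim = dims)
  with_seed(5, {
    v[] <- rnorm(prod(dims), 10000, 10)          # background clutter
    v[2:12, 2:12, ] <- rnorm(11 * 11 * 12, 2000, 10)
    lab[2:12, 2:12, ] <- 1L
    v[20:32, 20:32, ] <- rnorm(13 * 13 * 12, 30000, 10)
    lab[20:32, 20:32, ] <- 2L
  })
  vol <- attenuation_volume(v, 0.8, region_labels = lab)
  cal <- calibrate_scan(vol)
  expect_equal(cal$mu_air, 2000, tolerance = 1e-3)
  expect_equal(cal$mu_calcite, 30000, tolerance = 1e-3)
  # erosion shrinks an 11x11x12 box to 9x9x10
  expect_equal(cal$n_air, 9 * 9 * 10)
  expect_equal(cal$n_calcite, 11 * 11 * 10)

  # too-small region errors
  lab2 <- array(0L, dim = dims)
  lab2[1:3, 1:3, 1:3] <- 1L
  lab2[20:32, 20:32, ] <- 2L
  vol2 <- attenuation_volume(v, 0.8, region_labels = lab2)
  expect_error(calibrate_scan(vol2), "too small")
})

test_that("auto-detection finds the standard block without labels", {
  dims <- c(48, 48, 12)
  v <- array(0, dim = dims)
  with_seed(6, {
    v[] <- rnorm(prod(dims), 2000, 15)           # air everywhere
    v[30:44, 30:44, 3:10] <- rnorm(15 * 15 * 8, 30000, 15)
  })
  vol <- attenuation_volume(v, 0.8)
  cal <- calibrate_scan(vol)
  expect_equal(cal$mu_calcite, 30000, tolerance = 1e-2)
  expect_equal(cal$mu_air, 2000, tolerance = 1e-2)

  flat <- attenuation_volume(array(rnorm(prod(dims), 2000, 1), dims), 0.8)
  expect_error(calibrate_scan(flat), "calibration failure")
})

test_that("gain-drifted repeat scans agree in CCN after calibration", {
  ph <- make_shell_phantom(shell_geometry(n_chambers = 1, r0 = 8, wall = 4,
                                          dims = c(32, 32, 16)))
  scene <- assemble_scene(list(ph), dims = c(96, 96, 16), voxel_size = 0.8)
  run <- function(gain) {
    sino <- simulate_scan(scene, beam_spectrum(gain_drift = gain),
                          n_angles = 90)
    rec <- reconstruct_fbp(sino)
    rec$region_labels <- scene$labels
    gray <- digitize_volume(rec, gain = gain)
    list(gray = gray, ccn = ccn_volume(gray))
  }
  a <- run(1.0)
  b <- run(1.12)
  m <- scene$specimen_masks[[1]]
  expect_equal(mean(b$gray$values[m]) / mean(a$gray$values[m]), 1.12,
               tolerance = 0.01)                  # raw grayscale drifts
  expect_equal(mean(b$ccn$values[m]), mean(a$ccn$values[m]),
               tolerance = 0.005)                 # CCN does not
})

test_that("segmentation recovers the phantom and excludes the standard", {
  ph <- make_shell_phantom(shell_geometry(n_chambers = 1, r0 = 10, wall = 4,
                                          dims = c(40, 40, 40)))
  scene <- assemble_scene(list(ph), dims = c(96, 96, 40), voxel_size = 0.8)
  sino <- simulate_scan(scene, monochromatic_spectrum(40), n_angles = 240)
  rec <- reconstruct_fbp(sino)
  rec$region_labels <- scene$labels
  cv <- ccn_volume(digitize_volume(rec))
  seg <- segment_shell(cv, min_component = 500)
  truth <- scene$specimen_masks[[1]]
  expect_lt(abs(sum(seg) / sum(truth) - 1), 0.05)
  expect_false(any(seg & scene$labels == 2L))    # standard excluded
  # idempotence: re-thresholding the mask-restricted histogram cannot grow it
  seg2 <- segment_shell(cv, min_component = 500)
  expect_identical(seg, seg2)

  air <- attenuation_volume(array(rnorm(40^3, 0, 5), c(40, 40, 40)), 0.8)
  expect_error(segment_shell(air), "segmentation failure")
})

test_that("specimen summaries are means over the mask with correct volume", {
  v <- array(0, dim = c(8, 8, 2))
  v[2, 3, 1] <- 795.0
  mask <- array(FALSE, dim = dim(v))
  mask[2, 3, 1] <- TRUE
  vol <- attenuation_volume(v, 0.8)
  s <- specimen_summary(vol, mask)
  expect_equal(s$mean_ccn, 795.0)
  expect_equal(s$shell_voxel_count, 1)
  expect_equal(s$shell_volume, 0.8^3)
  expect_equal(sum(s$ccn_histogram$counts), 1)
  expect_error(specimen_summary(vol, mask & FALSE), "empty")
})

test_that("density reconstruction is linear: half density gives half CCN", {
  ph <- make_shell_phantom(shell_geometry(n_chambers = 1, r0 = 10, wall = 4,
                                          dims = c(40, 40, 40)))
  half <- ph
  half$density <- ph$density / 2
  run <- function(p) {
    scene <- assemble_scene(list(p), dims = c(96, 96, 40), voxel_size = 0.8)
    sino <- simulate_scan(scene, monochromatic_spectrum(40), n_angles = 240)
    rec <- reconstruct_fbp(sino)
    rec$region_labels <- scene$labels
    list(ccn = ccn_volume(digitize_volume(rec)),
         mask = scene$specimen_masks[[1]])
  }
  a <- run(ph)
  b <- run(half)
  r_full <- mean(a$ccn$values[a$mask])
  r_half <- mean(b$ccn$values[b$mask])
  expect_equal(r_half / r_full, 0.5, tolerance = 0.02)
})

test_that("color slices are monotone and decode back within one bin", {
  # gradient slab across x
  n <- 32
  v <- array(rep(seq(0, 1000, length.out = n), times = n), dim = c(n, n, 1))
  vol <- attenuation_volume(v, 0.8)
  out <- withr::local_tempdir()
  paths <- density_slices(vol, axis = "z", out_dir = out)
  expect_true(file.exists(paths[1]))
  expect_true(file.exists(file.path(out, "palette.json")))
  expect_error(density_slices(vol, axis = "w", out_dir = out), "invalid axis")

  ccn_vals <- seq(0, 1000, by = 13)
  pal <- calciscan:::ccn_palette()
  idx <- 1 + floor((length(pal) - 1e-9) *
                     pmin(pmax(ccn_vals / 1000, 0), 1 - 1e-12))
  expect_true(all(diff(idx) >= 0))               # monotone mapping
  rgbm <- t(col2rgb(pal[idx]))
  dec <- decode_palette(rgbm)
  expect_lt(max(abs(dec - ccn_vals)), 1000 / length(pal))  # within one bin
})
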