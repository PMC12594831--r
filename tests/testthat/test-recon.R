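sp <- load_spectra()
tx <- transducer_spec()
acq <- acquisition_spec(seed = 1)

test_that("all-zero PA traces reconstruct to an all-zero image", {
  ph <- make_phantom(list(), grid_shape = c(60, 1, 60), voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  cd <- pa_channel_data(ph, NULL, tx, acq, 756, sp)
  img <- das_pa(cd, grid = image_grid(6, 6, 0.2))
  expect_true(all(img$pixels == 0))
})

test_that("das_pa matches a brute-force delay-and-sum oracle", {
  tx16 <- transducer_spec(n_elements = 16, pitch_mm = 0.3)
  ph <- point_source_phantom(0.05, 8.05, grid_shape = c(100, 1, 120))
  cd <- pa_channel_data(ph, NULL, tx16, acq, 796, sp)
  grid <- image_grid(4, 3, 0.2, z0_mm = 7)
  for (cfg in list(list(fnum = 1.0, apod = "hann"),
                   list(fnum = 0, apod = "rect"))) {
    img <- das_pa(cd, tx = tx16, grid = grid, fnum = cfg$fnum,
                  apodization = cfg$apod)
    oracle <- das_pa_oracle(cd, tx16, grid, fnum = cfg$fnum,
                            apodization = cfg$apod)
    expect_rel_equal(img$pixels, oracle, 1e-9)
  }
})

test_that("default reconstruction grid spans 40 x 20 mm", {
  g <- image_grid()
  expect_equal(g$extent_mm, c(40, 20))
  expect_equal(g$pixel_size_mm, 0.1)
  expect_equal(length(g$x), 400)
  expect_equal(length(g$z), 200)
})

test_that("point sources reconstruct at their true location (round trip)", {
  for (src in list(c(-5.05, 8.05), c(0.05, 15.05), c(6.05, 12.05))) {
    ph <- point_source_phantom(src[1], src[2], grid_shape = c(300, 1, 220))
    cd <- pa_channel_data(ph, NULL, tx, acq, 796, sp)
    grid <- image_grid(30, 20, 0.1)
    env <- envelope_image(das_pa(cd, grid = grid))
    pk <- which(env$pixels == max(env$pixels), arr.ind = TRUE)[1, ]
    expect_lte(abs(grid$z[pk[1]] - src[2]), 0.1 + 1e-9)
    expect_lte(abs(grid$x[pk[2]] - src[1]), 0.1 + 1e-9)
  }
})

test_that("das_pa is linear and invariant to the recorded receive gain", {
  ph <- point_source_phantom(0.05, 10.05, grid_shape = c(200, 1, 150))
  grid <- image_grid(10, 6, 0.2, z0_mm = 7)
  acq54 <- acquisition_spec(pa_gain_db = 54, seed = 1)
  acq0 <- acquisition_spec(pa_gain_db = 0, seed = 1)
  img54 <- das_pa(pa_channel_data(ph, NULL, tx, acq54, 796, sp), grid = grid)
  img0 <- das_pa(pa_channel_data(ph, NULL, tx, acq0, 796, sp), grid = grid)
  expect_rel_equal(img54$pixels, img0$pixels, 1e-9)
  # superposition on channel data
  cd <- pa_channel_data(ph, NULL, tx, acq54, 796, sp)
  cd2 <- cd
  cd2$traces <- 2 * cd$traces
  expect_equal(das_pa(cd2, grid = grid)$pixels, 2 * img54$pixels,
               tolerance = 1e-12)
})

test_that("US scatterer at focus reconstructs within one pixel", {
  ph <- make_phantom(list(), grid_shape = c(300, 1, 220), voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  ph$scatter_amp[151, 1, 200] <- 1
  true_xz <- voxel_center(ph, 151, 200)
  cd <- us_channel_data(ph, tx, acq, 0)
  grid <- image_grid(8, 4, 0.1, z0_mm = 18)
  env <- envelope_image(das_us(cd, grid = grid))
  pk <- which(env$pixels == max(env$pixels), arr.ind = TRUE)[1, ]
  expect_lte(abs(grid$z[pk[1]] - true_xz[2]), 0.1 + 1e-9)
  expect_lte(abs(grid$x[pk[2]] - true_xz[1]), 0.1 + 1e-9)
})

test_that("compounding three identical packets triples the image", {
  ph <- make_phantom(list(), grid_shape = c(200, 1, 150), voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  ph$scatter_amp[100, 1, 100] <- 1
  cd <- us_channel_data(ph, tx, acq, 0)
  grid <- image_grid(6, 4, 0.2, z0_mm = 8)
  one <- das_us(cd, grid = grid)
  three <- das_us(list(cd, cd, cd), grid = grid)
  expect_rel_equal(three$pixels, 3 * one$pixels, 1e-12)
})

test_that("compounded two-way lateral resolution is near the diffraction limit", {
  ph <- make_phantom(list(), grid_shape = c(300, 1, 220), voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  ph$scatter_amp[151, 1, 200] <- 1
  pks <- lapply(c(0, -10, 10), function(a) us_channel_data(ph, tx, acq, a))
  grid <- image_grid(6, 3, 0.02, z0_mm = 18.5)
  env <- envelope_image(das_us(pks, grid = grid))
  lat <- apply(env$pixels, 2, max)
  w <- fwhm(lat, 0.02)
  lambda_mm <- 1540 / 7e6 * 1e3
  est <- lambda_mm * 20 / (tx$n_elements * tx$pitch_mm)
  expect_lt(abs(w - est) / est, 0.30)
})

test_that("mismatched sampling rates across packets are rejected", {
  ph <- make_phantom(list(), grid_shape = c(100, 1, 100), voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  ph$scatter_amp[50, 1, 50] <- 1
  a <- us_channel_data(ph, tx, acq, 0)
  b <- us_channel_data(ph, tx, acquisition_spec(sampling_mhz = 50, seed = 1),
                       -10)
  expect_error(das_us(list(a, b)), "sampling")
})

test_that("envelope of a pure tone is flat and peaks map to 0 dB", {
  z <- seq_len(256)
  tone <- matrix(sin(2 * pi * (50 / 256) * z), ncol = 1)  # periodic tone
  grid <- list(extent_mm = c(0.1, 25.6), pixel_size_mm = 0.1,
               x = 0, z = z * 0.1)
  rf <- tripai:::new_bscan(tone, grid, "PA", "rf")
  env <- envelope_image(rf)
  ripple <- diff(range(env$pixels[20:236, 1])) / max(env$pixels)
  expect_lt(ripple, 0.01)
  db <- envelope_log(rf, 30)
  expect_equal(max(db$pixels), 0)
  expect_gte(min(db$pixels), -30)
})

test_that("envelope equals an independent FFT Hilbert oracle", {
  set.seed(7)
  n <- 200
  rfm <- matrix(stats::rnorm(n * 5), n, 5)
  env <- tripai:::envelope_matrix(rfm)
  for (j in 1:5) {
    expect_rel_equal(env[, j], hilbert_env_oracle(rfm[, j]), 1e-9)
  }
})

test_that("all-zero input to envelope_log warns and returns the floor", {
  grid <- list(extent_mm = c(1, 1), pixel_size_mm = 0.1,
               x = seq_len(10) * 0.1, z = seq_len(10) * 0.1)
  rf <- tripai:::new_bscan(matrix(0, 10, 10), grid, "US", "rf")
  expect_warning(db <- envelope_log(rf, 40), "all-zero")
  expect_true(all(db$pixels == -40))
})

test_that("frame_sequencer yields complete spectral cycles and flags gaps", {
  fx <- make_fixtures("two_tube", seed = 1)
  fr <- simulate_frame(fx$phantom, fx$tx, fx$acq, sp)
  run <- list(frames = list(fr), acq = fx$acq)
  bundles <- frame_sequencer(run)
  expect_length(bundles, 1)
  expect_length(bundles[[1]]$pa, 4)        # four-wavelength in-vitro cycle
  expect_length(bundles[[1]]$us, 3)
  # five-wavelength cycle
  acq5 <- acquisition_spec(seed = 1)
  fr5 <- simulate_frame(fx$phantom, fx$tx, acq5, sp)
  expect_length(frame_sequencer(list(frames = list(fr5),
                                     acq = acq5))[[1]]$pa, 5)
  # empty container
  expect_equal(frame_sequencer(list(frames = list(), acq = fx$acq)), list())
  # missing wavelength
  broken <- fr
  broken$pa <- broken$pa[-2]
  expect_error(frame_sequencer(list(frames = list(broken), acq = fx$acq)),
               "incomplete spectral cycle in frame 1")
})

test_that("channel containers round-trip through write_run/read_run", {
  fx <- make_fixtures("two_tube", seed = 1)
  fr <- simulate_frame(fx$phantom, fx$tx, fx$acq, sp)
  path <- withr::local_tempfile(fileext = ".rds")
  write_run(list(fr), path, fx$tx, fx$acq)
  back <- read_run(path)
  expect_equal(back$frames[[1]]$pa[[1]]$traces, fr$pa[[1]]$traces)
  expect_equal(back$acq$wavelengths_nm, fx$acq$wavelengths_nm)
})
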