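sp <- load_spectra()
tx <- transducer_spec()
acq <- acquisition_spec(seed = 1)

test_that("analytic fluence is unity in the footprint of a lossless medium", {
  dims <- c(40, 20, 30)
  mua <- array(0, dims)
  phi <- fluence_analytic(mua, 0, 0.1, beam_model("coaxial"))
  # central column lies inside the footprint at every depth
  expect_true(all(phi[20, 10, ] == 1))
  expect_equal(max(phi), 1)
})

test_that("homogeneous medium: log-fluence is linear with slope -mu_eff", {
  dims <- c(40, 20, 60)
  mua <- array(0.01, dims)
  musp <- array(1.0, dims)
  phi <- fluence_analytic(mua, musp, 0.1, beam_model("coaxial"))
  z <- (seq_len(60) - 0.5) * 0.1
  lphi <- log(phi[20, 10, ])
  slope <- diff(lphi) / diff(z)
  mu_eff <- sqrt(3 * 0.01 * (0.01 + 1))
  expect_true(all(abs(slope + mu_eff) < 1e-6))
})

test_that("oblique 45-degree illumination delivers less fluence at depth", {
  dims <- c(60, 20, 50)
  mua <- array(0.01, dims)
  musp <- array(1.0, dims)
  phi_co <- fluence_analytic(mua, musp, 0.1, beam_model("coaxial"))
  phi_ob <- fluence_analytic(mua, musp, 0.1, beam_model("oblique"))
  max_co <- apply(phi_co, 3, max)
  max_ob <- apply(phi_ob, 3, max)
  expect_true(all(max_ob[-1] < max_co[-1]))
  expect_error(fluence_analytic(array(-1, dims), musp, 0.1,
                                beam_model("coaxial")),
               "nonnegative")
})

test_that("empty phantom with zero noise gives all-zero PA traces", {
  ph <- make_phantom(list(), grid_shape = c(60, 1, 60), voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  cd <- pa_channel_data(ph, NULL, tx, acq, 756, sp)
  expect_true(all(cd$traces == 0))
  expect_equal(cd$modality, "PA")
  expect_equal(cd$wavelength_nm, 756)
})

test_that("single-voxel source arrives at the geometric sample index", {
  ph <- point_source_phantom(0.05, 20.05, grid_shape = c(300, 1, 220))
  cd <- pa_channel_data(ph, NULL, tx, acq, 796, sp)
  # central element nearest x = 0.05 is element 33 at x = +0.15
  ex <- element_positions(tx)
  e <- which.min(abs(ex - 0.05))
  r <- sqrt((0.05 - ex[e])^2 + 20.05^2)
  expected <- round(40e6 * r * 1e-3 / 1540) + 1
  peak <- which.max(abs(cd$traces[e, ]))
  expect_lte(abs(peak - expected), 1)
})

test_that("ICG outshines blood at 756 nm given the shipped spectra", {
  blood <- vessel_spec(rbind(c(-4, 0.05, 3), c(-4, 0.05, 3)), 0.5, "blood",
                       so2 = 0.95)
  icg <- vessel_spec(rbind(c(4, 0.05, 3), c(4, 0.05, 3)), 0.5, "icg")
  ph <- make_phantom(list(blood, icg), grid_shape = c(200, 1, 100),
                     voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  cd <- pa_channel_data(ph, NULL, tx, acq, 756, sp)
  ex <- element_positions(tx)
  e_blood <- which.min(abs(ex - -4))
  e_icg <- which.min(abs(ex - 4))
  expect_gt(max(abs(cd$traces[e_icg, ])), 2 * max(abs(cd$traces[e_blood, ])))
})

test_that("PA forward model is linear in the initial pressure", {
  ph1 <- point_source_phantom(-2.05, 10.05, grid_shape = c(200, 1, 150))
  ph2 <- point_source_phantom(3.05, 12.05, grid_shape = c(200, 1, 150))
  both <- point_source_phantom(-2.05, 10.05, grid_shape = c(200, 1, 150))
  both$conc$ICG <- both$conc$ICG + ph2$conc$ICG
  t1 <- pa_channel_data(ph1, NULL, tx, acq, 796, sp)$traces
  t2 <- pa_channel_data(ph2, NULL, tx, acq, 796, sp)$traces
  tb <- pa_channel_data(both, NULL, tx, acq, 796, sp)$traces
  expect_equal(tb, t1 + t2, tolerance = 1e-12)
})

test_that("channel data are reproducible for a fixed seed", {
  ph <- point_source_phantom(0.05, 10.05, grid_shape = c(200, 1, 150))
  acqn <- acquisition_spec(noise_rms = 0.5, seed = 99)
  a <- pa_channel_data(ph, NULL, tx, acqn, 756, sp)
  b <- pa_channel_data(ph, NULL, tx, acqn, 756, sp)
  expect_identical(a$traces, b$traces)
  acqn2 <- acquisition_spec(noise_rms = 0.5, seed = 100)
  c2 <- pa_channel_data(ph, NULL, tx, acqn2, 756, sp)
  expect_false(identical(a$traces, c2$traces))
})

test_that("zero scatterers give zero US traces; steering limit enforced", {
  ph <- make_phantom(list(), grid_shape = c(60, 1, 60), voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  cd <- us_channel_data(ph, tx, acq, 0)
  expect_true(all(cd$traces == 0))
  expect_error(us_channel_data(ph, tx, acq, 45), "steering")
})

test_that("on-axis scatterer at focus echoes at the round-trip sample", {
  ph <- make_phantom(list(), grid_shape = c(300, 1, 220), voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  ex <- element_positions(tx)
  # scatterer exactly on the axis of line 33 (x = 0.15) at the 20 mm focus
  ix <- round((ex[33] - ph$origin_mm[1]) / 0.1 + 0.5)
  iz <- 200
  ph$scatter_amp[ix, 1, iz] <- 1
  xz <- voxel_center(ph, ix, iz)
  cd <- us_channel_data(ph, tx, acq, 0, focal_mm = xz[2])
  tr <- cd$traces[33, 33, ]
  r <- xz[2]
  expected <- round(40e6 * 2 * r * 1e-3 / 1540) + 1
  expect_lte(abs(which.max(abs(tr)) - expected), 1)
})

test_that("two-way arrival geometry is mirror-symmetric about the array", {
  # scatterer at x = 0 (odd lateral grid): the (line, element) pair and its
  # left-right mirror must see identical round-trip arrival times
  ph <- make_phantom(list(), grid_shape = c(301, 1, 220), voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  ph$scatter_amp[151, 1, 150] <- 1
  cd <- us_channel_data(ph, tx, acq, 0)
  # lines 32/33 straddle the scatterer and illuminate it; elements mirrored
  for (pair in list(c(32, 20), c(32, 45), c(33, 10))) {
    i <- pair[1]; j <- pair[2]
    a <- which.max(abs(cd$traces[i, j, ]))
    b <- which.max(abs(cd$traces[65 - i, 65 - j, ]))
    expect_lte(abs(a - b), 1)
    expect_gt(max(abs(cd$traces[i, j, ])), 0)
  }
})

test_that("a frame emits one US packet per steering angle", {
  fx <- make_fixtures("two_tube", seed = 1)
  fr <- simulate_frame(fx$phantom, fx$tx, fx$acq, sp)
  expect_length(fr$us, 3)
  expect_equal(unname(vapply(fr$us, `[[`, numeric(1), "steer_angle_deg")),
               c(0, -10, 10))
  expect_length(fr$pa, 4)
})

test_that("fluorescence projection follows round-trip attenuation", {
  ph <- make_phantom(list(), grid_shape = c(60, 1, 120), voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  expect_true(all(fluorescence_frame(ph) == 0))   # no ICG
  d <- 2; atten <- 0.52
  ph$conc$ICG[30, 1, round(d / 0.1)] <- 1e-4
  ph2 <- ph; ph2$conc$ICG[] <- 0
  ph2$conc$ICG[30, 1, round(2 * d / 0.1)] <- 1e-4
  f1 <- fluorescence_frame(ph, atten_per_mm = atten)
  f2 <- fluorescence_frame(ph2, atten_per_mm = atten)
  expect_equal(max(f1) / max(f2), exp(2 * atten * d), tolerance = 1e-6)
  expect_error(fluorescence_frame(ph, excitation_nm = 500), "ICG")
})

test_that("tube detectability falls below 6 dB between 4.5 and 7.3 mm", {
  # contrast model: tube intensity at depth d over a 1e-3 relative camera
  # noise floor; SNR(d) = 20*log10(I(d)/floor) with the default attenuation
  depths <- seq(1, 10, by = 0.1)
  ph0 <- make_phantom(list(), grid_shape = c(40, 1, 110),
                      voxel_size_mm = 0.1,
                      background = list(scatter_density_mm3 = 0), seed = 1)
  i0 <- {
    p <- ph0; p$conc$ICG[20, 1, 1] <- 1e-4
    max(fluorescence_frame(p))
  }
  floor_level <- 1e-3 * i0
  snr_db <- vapply(depths, function(d) {
    p <- ph0
    p$conc$ICG[20, 1, round(d / 0.1)] <- 1e-4
    20 * log10(max(fluorescence_frame(p)) / floor_level)
  }, numeric(1))
  crossing <- depths[max(which(snr_db >= 6))]
  expect_gt(crossing, 4.5)
  expect_lt(crossing, 7.3)
})
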