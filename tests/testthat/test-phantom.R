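test_that("empty vessel list gives pure background with zero ICG", {
  ph <- make_phantom(list(), grid_shape = c(50, 2, 40), voxel_size_mm = 0.2,
                     seed = 3)
  expect_true(all(ph$conc$ICG == 0))
  expect_true(all(ph$conc$Hb == 0))
  expect_true(all(ph$conc$HbO2 == 0))
  expect_true(all(ph$scatter_amp >= 0))
})

test_that("tube voxelization matches a brute-force point-in-cylinder count", {
  v <- vessel_spec(rbind(c(-4, 0.05, 3), c(4, 0.05, 3)), 0.5, "icg")
  ph <- make_phantom(list(v), grid_shape = c(120, 1, 60),
                     voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  got <- sum(ph$conc$ICG > 0)
  # exhaustive oracle over every voxel center against the capsule inequality
  cx <- ph$origin_mm[1] + (seq_len(120) - 0.5) * 0.1
  cy <- ph$origin_mm[2] + (1 - 0.5) * 0.1
  cz <- ph$origin_mm[3] + (seq_len(60) - 0.5) * 0.1
  n_oracle <- 0
  for (i in seq_along(cx)) for (k in seq_along(cz)) {
    x <- cx[i]; z <- cz[k]
    tproj <- min(max((x - -4) / 8, 0), 1)
    px <- -4 + tproj * 8
    d <- sqrt((x - px)^2 + (cy - 0.05)^2 + (z - 3)^2)
    if (d <= 0.5) n_oracle <- n_oracle + 1
  }
  expect_equal(got, n_oracle)
  # connectivity: all ICG voxels lie in one z-x slab around the axis
  idx <- which(ph$conc$ICG > 0, arr.ind = TRUE)
  expect_true(all(abs(cz[idx[, 3]] - 3) <= 0.5 + 1e-9))
})

test_that("blood vessel concentrations encode so2 exactly", {
  v <- vessel_spec(rbind(c(0, 0.05, 3), c(0, 0.05, 3)), 0.5, "blood",
                   so2 = 0.37)
  ph <- make_phantom(list(v), grid_shape = c(60, 1, 60), voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  inside <- ph$conc$HbO2 > 0
  frac <- ph$conc$HbO2[inside] / (ph$conc$HbO2[inside] + ph$conc$Hb[inside])
  expect_equal(unique(round(frac, 12)), 0.37)
})

test_that("two-tube benchmark scene carries blood and ICG at 3 mm depth", {
  fx <- make_fixtures("two_tube", seed = 5)
  ph <- fx$phantom
  cz <- ph$origin_mm[3] + (seq_len(ph$grid_shape[3]) - 0.5) * ph$voxel_size_mm
  izb <- which(ph$conc$Hb > 0, arr.ind = TRUE)[, 3]
  izi <- which(ph$conc$ICG > 0, arr.ind = TRUE)[, 3]
  expect_true(all(abs(cz[izb] - 3) <= 0.6))
  expect_true(all(abs(cz[izi] - 3) <= 0.6))
  expect_gt(sum(ph$scatter_amp > 0), 0)   # speckle background present
})

test_that("vessels outside the grid or below resolution are rejected", {
  too_deep <- vessel_spec(rbind(c(0, 0.05, 9.9), c(0, 0.05, 9.9)), 0.5, "icg")
  expect_error(make_phantom(list(too_deep), grid_shape = c(60, 1, 100),
                            voxel_size_mm = 0.1, seed = 1),
               "outside")
  thin <- vessel_spec(rbind(c(0, 0.05, 3), c(0, 0.05, 3)), 0.15, "icg")
  expect_error(make_phantom(list(thin), grid_shape = c(60, 1, 100),
                            voxel_size_mm = 0.1, seed = 1),
               "resolution")
})

test_that("total ICG amount matches the analytic capsule volume within 5%", {
  r <- 0.4   # 4 voxels
  len <- 8
  v <- vessel_spec(rbind(c(-len / 2, 0.5, 3), c(len / 2, 0.5, 3)), r, "icg",
                   total_conc_M = 1e-4)
  ph <- make_phantom(list(v), grid_shape = c(120, 10, 60),
                     voxel_size_mm = 0.1,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  vol_analytic_mm3 <- pi * r^2 * len + 4 / 3 * pi * r^3   # cylinder + caps
  amount_analytic <- vol_analytic_mm3 * 1e-6 * 1e-4
  expect_lt(abs(phantom_amount(ph, "ICG") - amount_analytic) /
              amount_analytic, 0.05)
})

test_that("identical seed and specs give a bit-identical phantom", {
  v <- list(vessel_spec(rbind(c(-2, 0.05, 3), c(2, 0.05, 4)), 0.5, "blood"))
  a <- make_phantom(v, grid_shape = c(80, 1, 60), voxel_size_mm = 0.1,
                    seed = 42)
  b <- make_phantom(v, grid_shape = c(80, 1, 60), voxel_size_mm = 0.1,
                    seed = 42)
  expect_identical(a, b)
  d <- make_phantom(v, grid_shape = c(80, 1, 60), voxel_size_mm = 0.1,
                    seed = 43)
  expect_false(identical(a$scatter_amp, d$scatter_amp))
})

test_that("absorption map is background plus a linear chromophore term", {
  sp <- load_spectra()
  ph <- make_phantom(list(), grid_shape = c(20, 1, 20), voxel_size_mm = 0.2,
                     background = list(mua_mm = 0.013,
                                       scatter_density_mm3 = 0), seed = 1)
  mua0 <- absorption_map(ph, 756, sp)
  expect_true(all(mua0 == 0.013))           # zero concentrations
  ph$conc$Hb[5, 1, 7] <- 1
  mua1 <- absorption_map(ph, 756, sp, include_background = FALSE)
  # scalar-product oracle: ln(10) * eps(756) * 1 mol/L / 10 mm/cm
  expect_equal(mua1[5, 1, 7], log(10) * eps_at(sp, 756, "Hb") / 10)
  # doubling concentrations doubles the chromophore term everywhere
  ph2 <- ph
  ph2$conc <- lapply(ph$conc, `*`, 2)
  expect_equal(absorption_map(ph2, 756, sp, include_background = FALSE),
               2 * mua1)
  expect_error(absorption_map(ph, 950, sp), "coverage")
})

test_that("pulsatile modulation is zero-mean and respects Nyquist", {
  expect_error(dynamics_spec(heart_rate_bpm = 84, frame_rate_hz = 2),
               "Nyquist")
  dyn <- dynamics_spec(heart_rate_bpm = 84, modulation_depth = 0,
                       frame_rate_hz = 20, n_frames = 10)
  art <- vessel_spec(rbind(c(0, 0.05, 4), c(0, 0.05, 4)), 0.6, "blood",
                     pulsatile = TRUE)
  ph <- make_phantom(list(art), grid_shape = c(80, 1, 80),
                     voxel_size_mm = 0.1, seed = 2)
  snap <- modulate_pulsatile(ph, dyn, 3)
  attr(snap, "scale") <- NULL
  expect_identical(snap, ph)               # zero depth: static scene
  # the pulse train itself: zero mean, unit max, 1.4 Hz fundamental at 84 bpm
  t <- seq(0, 1 / 1.4, length.out = 20001)[-1]
  s <- pulse_train(t, 1.4)
  expect_lt(abs(mean(s)), 1e-3)
  expect_equal(max(s), 1, tolerance = 1e-4)
  # analytic mean cross-section area over one period within 1% of static
  dyn2 <- dynamics_spec(heart_rate_bpm = 84, modulation_depth = 0.15,
                        frame_rate_hz = 20, n_frames = 200)
  g <- 1 + 0.15 * s
  expect_lt(abs(mean(g^2) - 1), 0.01)
  # modulated snapshot scales the pulsatile vessel only
  snap2 <- modulate_pulsatile(ph, dyn2, 1)
  gf <- attr(snap2, "scale")
  expect_equal(max(snap2$conc$HbO2), max(ph$conc$HbO2) * gf)
  expect_error(modulate_pulsatile(ph, dyn2, 200), "frame_index")
})

test_that("phantom round-trips through NIfTI + YAML scene files", {
  skip_if_not_installed("RNifti")
  dir <- withr::local_tempdir()
  v <- list(vessel_spec(rbind(c(0, 0.05, 3), c(0, 0.05, 3)), 0.5, "icg"))
  ph <- make_phantom(v, grid_shape = c(40, 1, 40), voxel_size_mm = 0.1,
                     seed = 1)
  paths <- write_phantom(ph, dir)
  expect_true(all(file.exists(paths)))
  back <- RNifti::readNifti(file.path(dir, "conc_ICG.nii.gz"))
  expect_equal(as.array(back), ph$conc$ICG, ignore_attr = TRUE)
  scene <- yaml::read_yaml(file.path(dir, "scene.yaml"))
  expect_equal(scene$vessels[[1]]$radius_mm, 0.5)
})
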