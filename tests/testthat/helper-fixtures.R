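# shared fixture builders and independent oracles

# phantom with a single point source voxel (no speckle) at (x_mm, z_mm)
point_source_phantom <- function(x_mm, z_mm, grid_shape = c(300, 1, 220),
                                 voxel_size_mm = 0.1, species = "ICG",
                                 conc = 1e-4) {
  ph <- make_phantom(list(), grid_shape = grid_shape,
                     voxel_size_mm = voxel_size_mm,
                     background = list(scatter_density_mm3 = 0), seed = 1)
  ix <- round((x_mm - ph$origin_mm[1]) / voxel_size_mm + 0.5)
  iz <- round((z_mm - ph$origin_mm[3]) / voxel_size_mm + 0.5)
  ph$conc[[species]][ix, 1, iz] <- conc
  ph
}

# voxel-center coordinates actually used for a phantom index
voxel_center <- function(ph, ix, iz) {
  c(ph$origin_mm[1] + (ix - 0.5) * ph$voxel_size_mm,
    ph$origin_mm[3] + (iz - 0.5) * ph$voxel_size_mm)
}

# independent brute-force delay-and-sum (R loops + approx), mirroring the
# documented das_pa contract: one-way delays, linear interpolation,
# dynamic-aperture apodization, gain normalization
das_pa_oracle <- function(channel, tx, grid, fnum = 1.0,
                          apodization = "hann", c_mps = 1540) {
  ex <- element_positions(tx)
  fs <- channel$sampling_mhz * 1e6
  nt <- ncol(channel$traces)
  img <- matrix(0, length(grid$z), length(grid$x))
  for (ix in seq_along(grid$x)) {
    for (iz in seq_along(grid$z)) {
      px <- grid$x[ix]; pz <- grid$z[iz]
      half_ap <- if (fnum > 0) pz / (2 * fnum) else 1e9
      acc <- 0
      for (e in seq_along(ex)) {
        d <- abs(px - ex[e])
        if (d > half_ap) next
        w <- if (apodization == "hann") 0.5 + 0.5 * cos(pi * d / half_ap) else 1
        r <- sqrt((px - ex[e])^2 + pz^2)
        idx <- (r * 1e-3 / c_mps - channel$t0_s) * fs
        if (idx < 0 || idx > nt - 1) next
        i <- floor(idx); f <- idx - i
        v <- if (i >= nt - 1) channel$traces[e, nt]
             else (1 - f) * channel$traces[e, i + 1] + f * channel$traces[e, i + 2]
        acc <- acc + w * v
      }
      img[iz, ix] <- acc
    }
  }
  img * 10^(-channel$gain_db / 20)
}

# independent FFT-based analytic-signal magnitude for one column
hilbert_env_oracle <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

expect_rel_equal <- function(a, b, tol) {
  expect_lt(max(abs(a - b)) / max(abs(b)), tol)
}
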