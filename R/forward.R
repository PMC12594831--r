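#' Transducer array specification
#'
#' Defaults describe a 64-element linear array at 300 um pitch with a 7 MHz
#' center frequency and 45% fractional (-6 dB) bandwidth.
#'
#' @param n_elements number of elements.
#' @param pitch_mm element pitch, mm.
#' @param center_freq_mhz center frequency, MHz.
#' @param frac_bandwidth -6 dB fractional bandwidth (0, 2).
#' @param elevational_focus_mm elevational focus, mm, or `NULL`.
#' @return a `transducer_spec`.
#' @export
transducer_spec <- function(n_elements = 64L, pitch_mm = 0.3,
                            center_freq_mhz = 7, frac_bandwidth = 0.45,
                            elevational_focus_mm = NULL) {
  stopifnot(n_elements >= 2, pitch_mm > 0, center_freq_mhz > 0,
            frac_bandwidth > 0, frac_bandwidth < 2)
  structure(list(n_elements = as.integer(n_elements), pitch_mm = pitch_mm,
                 center_freq_mhz = center_freq_mhz,
                 frac_bandwidth = frac_bandwidth,
                 elevational_focus_mm = elevational_focus_mm),
            class = "transducer_spec")
}

#' Element center positions (mm, lateral, array centered at x = 0)
#' @param tx a `transducer_spec`.
#' @export
element_positions <- function(tx) {
  (seq_len(tx$n_elements) - (tx$n_elements + 1) / 2) * tx$pitch_mm
}

# Gaussian envelope sigma (s) giving a -6 dB two-sided amplitude spectral
# width of frac_bandwidth * f0
pulse_sigma_t <- function(tx) {
  df <- tx$frac_bandwidth * tx$center_freq_mhz * 1e6
  (2 / (pi * df)) * sqrt(log(2) / 2)
}

#' Acquisition specification
#'
#' Defaults mirror a 20 Hz trimodal sequence: passive PA receive on each
#' laser shot, followed 100 us later by three steered line-beam US packets
#' (0, -10, +10 degrees), with receive gains of 54 dB (PA) and 39 dB (US).
#'
#' @param sampling_mhz receive sampling rate (must exceed 4x the transducer
#'   center frequency).
#' @param frame_rate_hz frame rate.
#' @param pa_gain_db,us_gain_db receive gains, dB.
#' @param steer_angles_deg US steering angles.
#' @param wavelengths_nm spectral cycle: five wavelengths
#'   (690, 756, 796, 820, 866) for in-vivo style sO2 work, or the four
#'   wavelength set (690, 720, 756, 796) for in-vitro style scenes.
#' @param pa_us_delay_us delay between a PA event and its US packets, us.
#' @param noise_rms additive white Gaussian channel noise RMS (post-gain
#'   units).
#' @param seed integer seed for the noise generator.
#' @return an `acquisition_spec`.
#' @export
acquisition_spec <- function(sampling_mhz = 40, frame_rate_hz = 20,
                             pa_gain_db = 54, us_gain_db = 39,
                             steer_angles_deg = c(0, -10, 10),
                             wavelengths_nm = c(690, 756, 796, 820, 866),
                             pa_us_delay_us = 100, noise_rms = 0,
                             seed = 1L) {
  stopifnot(sampling_mhz > 0, noise_rms >= 0)
  if (is.unsorted(wavelengths_nm, strictly = TRUE)) {
    stop("wavelengths_nm must be ascending and unique")
  }
  structure(list(sampling_mhz = sampling_mhz, frame_rate_hz = frame_rate_hz,
                 pa_gain_db = pa_gain_db, us_gain_db = us_gain_db,
                 steer_angles_deg = steer_angles_deg,
                 wavelengths_nm = wavelengths_nm,
                 pa_us_delay_us = pa_us_delay_us, noise_rms = noise_rms,
                 seed = as.integer(seed)),
            class = "acquisition_spec")
}

check_sampling <- function(tx, acq) {
  if (acq$sampling_mhz <= 4 * tx$center_freq_mhz) {
    stop("sampling_mhz must exceed 4x the transducer center frequency")
  }
}

#' Illumination beam model
#'
#' `"coaxial"` is the transparent-transducer geometry (normal incidence
#' through the array); `"oblique"` is the conventional side illumination
#' (default 45 degree incidence, beam axis offset 4 mm from the array).
#'
#' @param kind `"coaxial"` or `"oblique"`.
#' @param fiber_diameter_mm source width, mm.
#' @param divergence_full_angle_deg full divergence angle, degrees.
#' @param incidence_angle_deg angle from the surface normal; defaults 0
#'   (coaxial) or 45 (oblique).
#' @param standoff_offset_mm lateral offset of the beam entry point from the
#'   array axis; defaults 0 (coaxial) or 4 (oblique).
#' @param wavelength_nm optical wavelength, nm.
#' @return a `beam_model`.
#' @export
beam_model <- function(kind = c("coaxial", "oblique"), fiber_diameter_mm = 1,
                       divergence_full_angle_deg = 40,
                       incidence_angle_deg = NULL, standoff_offset_mm = NULL,
                       wavelength_nm = 750) {
  kind <- match.arg(kind)
  if (is.null(incidence_angle_deg)) {
    incidence_angle_deg <- if (kind == "coaxial") 0 else 45
  }
  if (is.null(standoff_offset_mm)) {
    standoff_offset_mm <- if (kind == "coaxial") 0 else 4
  }
  if (incidence_angle_deg < 0 || incidence_angle_deg >= 90) {
    stop("incidence_angle_deg must be in [0, 90)")
  }
  structure(list(kind = kind, fiber_diameter_mm = fiber_diameter_mm,
                 divergence_full_angle_deg = divergence_full_angle_deg,
                 incidence_angle_deg = incidence_angle_deg,
                 standoff_offset_mm = standoff_offset_mm,
                 wavelength_nm = wavelength_nm),
            class = "beam_model")
}

#' Analytic broad-beam fluence (diffusion approximation)
#'
#' Fast stand-in for Monte Carlo transport: along the beam axis
#' `Phi = exp(-mu_eff * z_eff)` with
#' `mu_eff = sqrt(3 * mua * (mua + mus'))` computed from depth-averaged
#' (cumulative plane-mean) coefficients, `z_eff` the path length along the
#' incidence direction. The lateral profile is 1 inside the diverging beam
#' footprint with a cosine rolloff at the edge. Values are at most 1 (unity
#' at the entry surface inside the footprint); no per-volume rescaling is
#' applied, so fluence maps from different beam geometries are directly
#' comparable.
#'
#' @param mua 3-D absorption grid, mm^-1.
#' @param mus_prime 3-D reduced-scattering grid (or scalar), mm^-1.
#' @param voxel_size_mm voxel size.
#' @param beam a [beam_model()].
#' @param origin_mm grid origin (x0, y0, z0); defaults to x centered, z = 0
#'   at the surface.
#' @return 3-D fluence array, unit maximum.
#' @export
fluence_analytic <- function(mua, mus_prime, voxel_size_mm, beam,
                             origin_mm = NULL) {
  dims <- dim(mua)
  if (length(mus_prime) == 1) mus_prime <- array(mus_prime, dim = dims)
  if (any(mua < 0) || any(mus_prime < 0)) {
    stop("optical coefficients must be nonnegative")
  }
  if (is.null(origin_mm)) origin_mm <- phantom_origin(dims, voxel_size_mm)
  cx <- origin_mm[1] + (seq_len(dims[1]) - 0.5) * voxel_size_mm
  cy <- origin_mm[2] + (seq_len(dims[2]) - 0.5) * voxel_size_mm
  cz <- origin_mm[3] + (seq_len(dims[3]) - 0.5) * voxel_size_mm
  inc <- beam$incidence_angle_deg * pi / 180
  # depth-averaged coefficients (cumulative plane means)
  mua_z <- apply(mua, 3, mean)
  mus_z <- apply(mus_prime, 3, mean)
  mua_bar <- cumsum(mua_z) / seq_along(mua_z)
  mus_bar <- cumsum(mus_z) / seq_along(mus_z)
  mu_eff <- sqrt(3 * mua_bar * (mua_bar + mus_bar))   # mm^-1
  half_div <- beam$divergence_full_angle_deg * pi / 360
  y_center <- mean(range(cy))
  out <- array(0, dim = dims)
  for (k in seq_len(dims[3])) {
    z <- cz[k]
    z_eff <- z / cos(inc)
    ax <- -beam$standoff_offset_mm + z * tan(inc)   # beam axis at this depth
    w <- beam$fiber_diameter_mm / 2 + z_eff * tan(half_div)
    edge <- pmax(0.25 * w, voxel_size_mm)
    dx <- abs(cx - ax) * cos(inc)
    dy <- abs(cy - y_center)
    px <- ifelse(dx <= w, 1,
                 ifelse(dx <= w + edge, 0.5 * (1 + cos(pi * (dx - w) / edge)), 0))
    py <- ifelse(dy <= w, 1,
                 ifelse(dy <= w + edge, 0.5 * (1 + cos(pi * (dy - w) / edge)), 0))
    out[, , k] <- outer(px, py) * exp(-mu_eff[k] * z_eff)
  }
  # entry-surface fluence inside the footprint is 1 by construction, so the
  # grid maximum is <= 1; no per-volume rescaling (would break comparisons
  # between beam geometries)
  out
}

trace_length <- function(phantom, tx, acq, two_way = FALSE) {
  ex <- element_positions(tx)
  hi <- phantom$origin_mm + phantom$grid_shape * phantom$voxel_size_mm
  r_max <- sqrt(max(abs(phantom$origin_mm[1] - max(ex)),
                    abs(hi[1] - min(ex)))^2 + hi[3]^2)
  t_max <- (if (two_way) 2 else 1) * r_max * 1e-3 / phantom$sound_speed_mps
  ceiling((t_max + 10 * pulse_sigma_t(tx)) * acq$sampling_mhz * 1e6)
}

#' Simulate photoacoustic channel data at one wavelength
#'
#' Initial pressure `p0 = Gamma * mua * Phi` (Grueneisen constant fixed at 1,
#' relative units; `mua` from the chromophore concentrations only, so an
#' empty phantom radiates nothing). Each source voxel of the selected
#' elevational slice contributes a spherically spreading band-limited pulse
#' to every element within a +/-45 degree acceptance cone; the receive gain
#' is applied as a linear multiplier and additive white Gaussian noise is
#' drawn with the acquisition seed.
#'
#' @param phantom a `digital_phantom`.
#' @param fluence 3-D fluence grid co-registered with the phantom (e.g. from
#'   [fluence_analytic()]), or `NULL` for uniform illumination.
#' @param tx a [transducer_spec()].
#' @param acq an [acquisition_spec()].
#' @param wavelength_nm acquisition wavelength.
#' @param spectra a `spectra_table`.
#' @param slice_iy elevational slice index (2.5-D acquisition).
#' @return a `channel_data` (modality `"PA"`, traces `[element, sample]`).
#' @export
pa_channel_data <- function(phantom, fluence, tx, acq, wavelength_nm,
                            spectra, slice_iy = 1L) {
  check_sampling(tx, acq)
  mua <- absorption_map(phantom, wavelength_nm, spectra,
                        include_background = FALSE)
  p0 <- if (is.null(fluence)) mua else mua * fluence
  sl <- p0[, slice_iy, ]
  idx <- which(sl > 0, arr.ind = TRUE)
  cx <- phantom$origin_mm[1] +
    (seq_len(phantom$grid_shape[1]) - 0.5) * phantom$voxel_size_mm
  cz <- phantom$origin_mm[3] +
    (seq_len(phantom$grid_shape[3]) - 0.5) * phantom$voxel_size_mm
  ex <- element_positions(tx)
  fs <- acq$sampling_mhz * 1e6
  n_samples <- trace_length(phantom, tx, acq, two_way = FALSE)
  if (nrow(idx)) {
    traces <- cpp_pa_forward(cx[idx[, 1]], cz[idx[, 2]], sl[idx],
                             ex, fs, n_samples, phantom$sound_speed_mps,
                             tx$center_freq_mhz * 1e6, pulse_sigma_t(tx),
                             0, phantom$voxel_size_mm / 2)
  } else {
    traces <- matrix(0, length(ex), n_samples)
  }
  gain <- 10^(acq$pa_gain_db / 20)
  traces <- traces * gain
  if (acq$noise_rms > 0) {
    set.seed(acq$seed + round(wavelength_nm))
    traces <- traces + stats::rnorm(length(traces), sd = acq$noise_rms)
  }
  structure(list(traces = traces, modality = "PA",
                 wavelength_nm = wavelength_nm, steer_angle_deg = NULL,
                 t0_s = 0, sampling_mhz = acq$sampling_mhz,
                 gain_db = acq$pa_gain_db, tx = tx, acq = acq,
                 provenance = list(seed = acq$seed, slice_iy = slice_iy,
                                   n_sources = nrow(idx))),
            class = "channel_data")
}

#' Simulate ultrasound channel data for one steered packet
#'
#' Two-way model: 64 focused line-beam transmits sweep the aperture left to
#' right at the packet's steering angle (virtual source at the 20 mm focus);
#' every grid scatterer echoes back to all elements with 1/r spreading each
#' way and the band-limited pulse.
#'
#' @inheritParams pa_channel_data
#' @param angle_deg steering angle (|angle| <= 30).
#' @param focal_mm transmit focal depth, mm.
#' @param beam_sigma_mm lateral Gaussian sigma of the transmitted line beam;
#'   default `0.45 * lambda * focal / aperture`.
#' @return a `channel_data` (modality `"US"`, traces `[line, element,
#'   sample]`).
#' @export
us_channel_data <- function(phantom, tx, acq, angle_deg = 0, focal_mm = 20,
                            beam_sigma_mm = NULL, slice_iy = 1L) {
  check_sampling(tx, acq)
  if (abs(angle_deg) > 30) stop("steering angle beyond +/-30 degree limit")
  sl <- phantom$scatter_amp[, slice_iy, ]
  idx <- which(sl > 0, arr.ind = TRUE)
  cx <- phantom$origin_mm[1] +
    (seq_len(phantom$grid_shape[1]) - 0.5) * phantom$voxel_size_mm
  cz <- phantom$origin_mm[3] +
    (seq_len(phantom$grid_shape[3]) - 0.5) * phantom$voxel_size_mm
  ex <- element_positions(tx)
  fs <- acq$sampling_mhz * 1e6
  n_samples <- trace_length(phantom, tx, acq, two_way = TRUE)
  lambda_mm <- phantom$sound_speed_mps / (tx$center_freq_mhz * 1e6) * 1e3
  if (is.null(beam_sigma_mm)) {
    beam_sigma_mm <- 0.45 * lambda_mm * focal_mm /
      (tx$n_elements * tx$pitch_mm)
  }
  if (nrow(idx)) {
    traces <- cpp_us_forward(cx[idx[, 1]], cz[idx[, 2]], sl[idx], ex, ex,
                             angle_deg * pi / 180, focal_mm, fs, n_samples,
                             phantom$sound_speed_mps,
                             tx$center_freq_mhz * 1e6, pulse_sigma_t(tx),
                             beam_sigma_mm, phantom$voxel_size_mm / 2)
  } else {
    traces <- array(0, dim = c(length(ex), length(ex), n_samples))
  }
  gain <- 10^(acq$us_gain_db / 20)
  traces <- traces * gain
  if (acq$noise_rms > 0) {
    set.seed(acq$seed + 7919L + round(angle_deg))
    traces <- traces + stats::rnorm(length(traces), sd = acq$noise_rms)
  }
  structure(list(traces = traces, modality = "US", wavelength_nm = NULL,
                 steer_angle_deg = angle_deg, focal_mm = focal_mm,
                 beam_sigma_mm = beam_sigma_mm,
                 t0_s = 0, event_offset_us = acq$pa_us_delay_us,
                 sampling_mhz = acq$sampling_mhz, gain_db = acq$us_gain_db,
                 tx = tx, acq = acq,
                 provenance = list(seed = acq$seed, slice_iy = slice_iy,
                                   n_scatterers = nrow(idx))),
            class = "channel_data")
}

#' @export
print.channel_data <- function(x, ...) {
  d <- dim(x$traces)
  cat("channel_data:", x$modality,
      if (x$modality == "PA") paste0("@", x$wavelength_nm, " nm")
      else paste0("@", x$steer_angle_deg, " deg"),
      "| traces", paste(d, collapse = " x "),
      "| fs", x$sampling_mhz, "MHz | gain", x$gain_db, "dB\n")
  invisible(x)
}

#' Simulate an en-face fluorescence frame
#'
#' Depth-weighted vertical projection of the ICG grid with round-trip
#' attenuation: `pixel(x, y) = sum_z ICG(x, y, z) * exp(-2 * atten * z)`.
#' The default attenuation is calibrated so that, against a relative camera
#' noise floor of 1e-3, tube contrast crosses a 6 dB detection threshold
#' near 6 mm depth (detectability fading between roughly 4.5 and 7.3 mm).
#'
#' @param phantom a `digital_phantom`.
#' @param excitation_nm excitation wavelength (must lie in the ICG band,
#'   650-900 nm).
#' @param atten_per_mm effective one-way attenuation coefficient, mm^-1.
#' @param camera optional list(nx, ny) for pixel re-binning; default native
#'   grid.
#' @return matrix `[x, y]` of en-face intensity with attribute
#'   `"pixel_size_mm"`.
#' @export
fluorescence_frame <- function(phantom, excitation_nm = 756,
                               atten_per_mm = 0.52, camera = NULL) {
  if (excitation_nm < 650 || excitation_nm > 900) {
    stop("excitation outside the ICG absorption band (650-900 nm)")
  }
  cz <- phantom$origin_mm[3] +
    (seq_len(phantom$grid_shape[3]) - 0.5) * phantom$voxel_size_mm
  wz <- exp(-2 * atten_per_mm * cz)
  icg <- phantom$conc$ICG
  img <- matrix(0, phantom$grid_shape[1], phantom$grid_shape[2])
  for (k in seq_len(phantom$grid_shape[3])) {
    img <- img + icg[, , k] * wz[k]
  }
  if (!is.null(camera)) {
    xi <- round(seq(1, nrow(img), length.out = camera$nx))
    yi <- round(seq(1, ncol(img), length.out = max(camera$ny, 1)))
    img <- img[xi, yi, drop = FALSE]
  }
  attr(img, "pixel_size_mm") <- phantom$voxel_size_mm
  img
}

#' Simulate one trimodal frame (spectral PA cycle + US packets + FL)
#'
#' One acquisition cycle: a PA event per wavelength, followed (pa_us_delay
#' later, recorded in the US `t0_s`) by one US packet per steering angle,
#' plus an en-face fluorescence frame.
#'
#' @inheritParams pa_channel_data
#' @param frame_index frame number stored in metadata.
#' @return a `trimodal_frame`: list with `pa` (per wavelength), `us` (per
#'   angle), `fl`, `frame_index`.
#' @export
simulate_frame <- function(phantom, tx, acq, spectra, fluence = NULL,
                           slice_iy = 1L, frame_index = 0L) {
  pa <- lapply(acq$wavelengths_nm, function(wl) {
    fl <- if (is.function(fluence)) fluence(wl) else fluence
    pa_channel_data(phantom, fl, tx, acq, wl, spectra, slice_iy)
  })
  names(pa) <- paste0(acq$wavelengths_nm, "nm")
  us <- lapply(acq$steer_angles_deg, function(a) {
    us_channel_data(phantom, tx, acq, angle_deg = a, slice_iy = slice_iy)
  })
  names(us) <- paste0(acq$steer_angles_deg, "deg")
  fl <- fluorescence_frame(phantom)
  structure(list(pa = pa, us = us, fl = fl,
                 frame_index = as.integer(frame_index),
                 wavelengths_nm = acq$wavelengths_nm,
                 steer_angles_deg = acq$steer_angles_deg),
            class = "trimodal_frame")
}

#' Write / read a raw channel-data container
#'
#' Serializes a list of `trimodal_frame`s plus acquisition metadata to a
#' single container file (RDS). Provenance (specs, seed, package version)
#' travels with the data.
#'
#' @param frames list of `trimodal_frame` objects.
#' @param path output path.
#' @param tx,acq the specs used to generate the frames.
#' @return `write_run`: invisibly, `path`. `read_run`: the container list.
#' @export
write_run <- function(frames, path, tx = NULL, acq = NULL) {
  run <- list(frames = frames, tx = tx, acq = acq,
              version = as.character(utils::packageVersion("tripai")))
  saveRDS(run, path)
  invisible(path)
}

#' @rdname write_run
#' @export
read_run <- function(path) readRDS(path)
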