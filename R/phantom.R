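#' Vessel specification
#'
#' Describes one tube-like structure (blood vessel or ICG-filled lymphatic)
#' by its centerline polyline and radius. For blood the Hb/HbO2 split is set
#' by the oxygen saturation: `C_HbO2 = so2 * total_conc`,
#' `C_Hb = (1 - so2) * total_conc`, so the recoverable ground truth
#' `C_HbO2 / (C_HbO2 + C_Hb)` equals `so2` exactly.
#'
#' @param centerline numeric matrix (n x 3) of points (x, y, z) in mm;
#'   x lateral (element axis, 0 at array center), y elevational, z axial
#'   depth (0 at the transducer face).
#' @param radius_mm tube radius, mm.
#' @param species `"blood"` or `"icg"`.
#' @param so2 oxygen saturation in `[0, 1]` (blood only).
#' @param total_conc_M total chromophore concentration, mol/L. Defaults:
#'   2.3e-3 (whole-blood total hemoglobin) for blood, 1e-4 for ICG.
#' @param echogenicity relative speckle amplitude inside the lumen
#'   (fluid-filled tubes are hypoechoic).
#' @param pulsatile logical; pulsatile vessels respond to
#'   [modulate_pulsatile()].
#' @return a `vessel_spec` object.
#' @export
vessel_spec <- function(centerline, radius_mm, species = c("blood", "icg"),
                        so2 = 0.95, total_conc_M = NULL,
                        echogenicity = 0.1, pulsatile = FALSE) {
  species <- match.arg(species)
  centerline <- matrix(as.numeric(centerline), ncol = 3)
  stopifnot(radius_mm > 0, nrow(centerline) >= 1)
  if (species == "blood" && (so2 < 0 || so2 > 1)) stop("so2 must be in [0, 1]")
  if (is.null(total_conc_M)) {
    total_conc_M <- if (species == "blood") 2.3e-3 else 1e-4
  }
  if (total_conc_M <= 0) stop("total_conc_M must be positive")
  mix <- if (species == "blood") {
    c(Hb = (1 - so2) * total_conc_M, HbO2 = so2 * total_conc_M, ICG = 0)
  } else {
    c(Hb = 0, HbO2 = 0, ICG = total_conc_M)
  }
  structure(list(centerline = centerline, radius_mm = radius_mm,
                 species = species, so2 = if (species == "blood") so2 else NA_real_,
                 species_mix = mix, echogenicity = echogenicity,
                 pulsatile = pulsatile),
            class = "vessel_spec")
}

#' Pulsatile dynamics specification
#'
#' @param heart_rate_bpm heart rate, beats per minute (default 84, i.e. a
#'   1.4 Hz fundamental).
#' @param modulation_depth fractional radius/concentration modulation in
#'   `[0, 1)`.
#' @param frame_rate_hz acquisition frame rate (default 20).
#' @param n_frames number of frames (default 200, a 10 s run at 20 Hz).
#' @param duty systolic fraction of the cardiac cycle occupied by the
#'   raised-cosine pulse.
#' @return a `dynamics_spec` object.
#' @export
dynamics_spec <- function(heart_rate_bpm = 84, modulation_depth = 0.15,
                          frame_rate_hz = 20, n_frames = 200, duty = 0.35) {
  stopifnot(heart_rate_bpm > 0, frame_rate_hz > 0, n_frames >= 1,
            modulation_depth >= 0, modulation_depth < 1,
            duty > 0, duty < 1)
  if (heart_rate_bpm / 60 >= frame_rate_hz / 2) {
    stop("heart rate ", heart_rate_bpm, " bpm is at or above the Nyquist ",
         "limit for a ", frame_rate_hz, " Hz frame rate")
  }
  structure(list(heart_rate_bpm = heart_rate_bpm,
                 modulation_depth = modulation_depth,
                 frame_rate_hz = frame_rate_hz, n_frames = n_frames,
                 duty = duty),
            class = "dynamics_spec")
}

#' Zero-mean raised-cosine pulse train
#'
#' Periodic systolic pulse used for arterial modulation: a raised cosine of
#' width `duty` cycles at the start of each period, shifted and scaled so the
#' waveform has zero mean over a period and unit maximum. A pulse train (not
#' a pure sinusoid) gives the harmonic-rich pulsation spectrum seen in vivo.
#'
#' @param t time, s (vectorized).
#' @param f0 fundamental frequency, Hz.
#' @param duty systolic fraction of the period.
#' @return numeric vector, zero-mean, max 1.
#' @export
pulse_train <- function(t, f0, duty = 0.35) {
  u <- (t * f0) %% 1
  p <- ifelse(u < duty, 0.5 * (1 - cos(2 * pi * u / duty)), 0)
  (p - 0.5 * duty) / (1 - 0.5 * duty)
}

phantom_origin <- function(grid_shape, voxel_size_mm) {
  c(-grid_shape[1] * voxel_size_mm / 2, 0, 0)
}

# distance from points (n x 3) to a polyline (m x 3); vectorized over points
dist_to_polyline <- function(pts, line) {
  d2 <- rep(Inf, nrow(pts))
  for (i in seq_len(max(1, nrow(line) - 1))) {
    a <- line[i, ]
    b <- if (nrow(line) > 1) line[i + 1, ] else line[i, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2, a)
    t <- if (len2 > 0) {
      pmin(1, pmax(0, as.vector(ap %*% ab) / len2))
    } else {
      rep(0, nrow(pts))
    }
    dx <- ap - outer(t, ab)
    d2 <- pmin(d2, rowSums(dx^2))
  }
  sqrt(d2)
}

#' Build a digital phantom
#'
#' Rasterizes tube-like vessels into per-species concentration grids and lays
#' down a fully developed speckle background: acoustic point scatterers at
#' uniform random sub-voxel positions with folded-Gaussian amplitudes,
#' accumulated per voxel. Deterministic given `seed`.
#'
#' Coordinates: x lateral (element axis, 0 at array center), y elevational,
#' z axial depth with z = 0 at the transducer face; voxels are half-open,
#' 0-based, `voxel_size_mm` isotropic.
#'
#' @param vessels list of [vessel_spec()] objects (may be empty).
#' @param grid_shape integer triple (nx, ny, nz).
#' @param voxel_size_mm isotropic voxel size, mm.
#' @param background list with `mua_mm` (background absorption, mm^-1),
#'   `mus_prime_mm` (reduced scattering, mm^-1), `scatter_density_mm3`
#'   (speckle scatterers per mm^3).
#' @param sound_speed_mps speed of sound, m/s.
#' @param seed integer seed for scatterer placement.
#' @return a `digital_phantom` object.
#' @export
make_phantom <- function(vessels = list(), grid_shape = c(200, 1, 100),
                         voxel_size_mm = 0.1,
                         background = list(mua_mm = 0.01, mus_prime_mm = 1.0,
                                           scatter_density_mm3 = 2),
                         sound_speed_mps = 1540, seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3, all(grid_shape >= 1), voxel_size_mm > 0)
  bg <- utils::modifyList(list(mua_mm = 0.01, mus_prime_mm = 1.0,
                               scatter_density_mm3 = 2), background)
  origin <- phantom_origin(grid_shape, voxel_size_mm)
  hi <- origin + grid_shape * voxel_size_mm

  species <- c("Hb", "HbO2", "ICG")
  conc <- lapply(species, function(s) array(0, dim = grid_shape))
  names(conc) <- species
  lumen <- array(FALSE, dim = grid_shape)   # inside-vessel mask
  pulsatile_mask <- array(FALSE, dim = grid_shape)

  # voxel centers, recycled in grid order (x fastest)
  cx <- origin[1] + (seq_len(grid_shape[1]) - 0.5) * voxel_size_mm
  cy <- origin[2] + (seq_len(grid_shape[2]) - 0.5) * voxel_size_mm
  cz <- origin[3] + (seq_len(grid_shape[3]) - 0.5) * voxel_size_mm

  for (v in vessels) {
    if (!inherits(v, "vessel_spec")) stop("vessels must be vessel_spec objects")
    if (v$radius_mm < 2 * voxel_size_mm) {
      stop("vessel radius ", v$radius_mm, " mm is below the resolution ",
           "floor of 2 voxels (", 2 * voxel_size_mm, " mm)")
    }
    cl <- v$centerline
    if (any(cl[, 1] - v$radius_mm < origin[1]) || any(cl[, 1] + v$radius_mm > hi[1]) ||
        any(cl[, 3] - v$radius_mm < origin[3]) || any(cl[, 3] + v$radius_mm > hi[3]) ||
        any(cl[, 2] < origin[2]) || any(cl[, 2] > hi[2])) {
      stop("vessel extends outside the phantom grid")
    }
    # bounding box in voxel indices, padded by the radius
    pad <- v$radius_mm + voxel_size_mm
    ix <- which(cx >= min(cl[, 1]) - pad & cx <= max(cl[, 1]) + pad)
    iy <- which(cy >= min(cl[, 2]) - pad & cy <= max(cl[, 2]) + pad)
    iz <- which(cz >= min(cl[, 3]) - pad & cz <= max(cl[, 3]) + pad)
    if (!length(ix) || !length(iy) || !length(iz)) next
    pts <- as.matrix(expand.grid(x = cx[ix], y = cy[iy], z = cz[iz]))
    inside <- dist_to_polyline(pts, cl) <= v$radius_mm
    if (!any(inside)) next
    idx <- as.matrix(expand.grid(ix, iy, iz))[inside, , drop = FALSE]
    for (s in species) {
      if (v$species_mix[[s]] > 0) conc[[s]][idx] <- v$species_mix[[s]]
    }
    lumen[idx] <- TRUE
    if (isTRUE(v$pulsatile)) pulsatile_mask[idx] <- TRUE
  }

  # speckle: random sub-voxel scatterers, folded-Gaussian amplitudes
  scatter_amp <- array(0, dim = grid_shape)
  vol_mm3 <- prod(grid_shape) * voxel_size_mm^3
  n_scat <- round(bg$scatter_density_mm3 * vol_mm3)
  if (n_scat > 0) {
    set.seed(as.integer(seed))
    pos <- cbind(stats::runif(n_scat, 0, grid_shape[1]),
                 stats::runif(n_scat, 0, grid_shape[2]),
                 stats::runif(n_scat, 0, grid_shape[3]))
    amp <- abs(stats::rnorm(n_scat))
    vox <- pmin(floor(pos), rep(grid_shape - 1L, each = n_scat)) + 1L
    lin <- vox[, 1] + grid_shape[1] * (vox[, 2] - 1L + grid_shape[2] * (vox[, 3] - 1L))
    acc <- rowsum(amp, lin)
    scatter_amp[as.integer(rownames(acc))] <- acc[, 1]
    # fluid lumina are hypoechoic relative to tissue speckle
    if (length(vessels)) {
      scatter_amp[lumen] <- scatter_amp[lumen] *
        min(vapply(vessels, `[[`, numeric(1), "echogenicity"))
    }
  }

  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 origin_mm = origin, conc = conc, scatter_amp = scatter_amp,
                 lumen = lumen, pulsatile_mask = pulsatile_mask,
                 mua_background_mm = bg$mua_mm,
                 mus_prime_background_mm = bg$mus_prime_mm,
                 sound_speed_mps = sound_speed_mps,
                 vessels = vessels, background = bg, seed = as.integer(seed)),
            class = "digital_phantom")
}

#' @export
print.digital_phantom <- function(x, ...) {
  cat("digital_phantom:", paste(x$grid_shape, collapse = " x "),
      "voxels @", x$voxel_size_mm, "mm;",
      length(x$vessels), "vessel(s)\n")
  for (s in names(x$conc)) {
    cat(sprintf("  %-5s max %.3g mol/L, %d positive voxels\n",
                s, max(x$conc[[s]]), sum(x$conc[[s]] > 0)))
  }
  invisible(x)
}

#' Optical absorption map at a wavelength
#'
#' Converts concentration grids to an absorption-coefficient grid:
#' `mua(v) = sum_n ln(10) * eps_n(lambda) * C_n(v) / 10` (decadic extinction
#' in cm^-1 M^-1, concentrations in mol/L, output in mm^-1), optionally plus
#' the homogeneous background absorption. Linear in the concentrations.
#'
#' @param phantom a `digital_phantom`.
#' @param wavelength_nm wavelength, nm (must lie within table coverage; no
#'   extrapolation).
#' @param spectra a `spectra_table`.
#' @param include_background add the phantom's background mua (default TRUE).
#' @return 3-D array of mua, mm^-1.
#' @export
absorption_map <- function(phantom, wavelength_nm, spectra,
                           include_background = TRUE) {
  mua <- array(if (include_background) phantom$mua_background_mm else 0,
               dim = phantom$grid_shape)
  for (s in names(phantom$conc)) {
    e <- eps_at(spectra, wavelength_nm, s)       # cm^-1 M^-1, decadic
    mua <- mua + log(10) * e * phantom$conc[[s]] / 10
  }
  mua
}

#' Pulsatile snapshot of a phantom
#'
#' Scales the radius and concentration of every pulsatile vessel by
#' `1 + modulation_depth * s(2 pi f0 t)`, where `s` is the zero-mean
#' raised-cosine pulse train ([pulse_train()]) and `f0 = heart_rate_bpm/60`,
#' then re-rasterizes. Non-pulsatile vessels and the speckle background
#' (same seed) are unchanged.
#'
#' @param phantom a `digital_phantom` built by [make_phantom()].
#' @param dynamics a [dynamics_spec()].
#' @param frame_index 0-based frame index, `< n_frames`.
#' @return a `digital_phantom` snapshot; attribute `"scale"` holds the
#'   applied modulation factor.
#' @export
modulate_pulsatile <- function(phantom, dynamics, frame_index) {
  stopifnot(inherits(phantom, "digital_phantom"),
            inherits(dynamics, "dynamics_spec"))
  frame_index <- as.integer(frame_index)
  if (frame_index < 0 || frame_index >= dynamics$n_frames) {
    stop("frame_index must be in [0, n_frames)")
  }
  t <- frame_index / dynamics$frame_rate_hz
  f0 <- dynamics$heart_rate_bpm / 60
  g <- 1 + dynamics$modulation_depth * pulse_train(t, f0, dynamics$duty)
  vessels <- lapply(phantom$vessels, function(v) {
    if (!isTRUE(v$pulsatile)) return(v)
    v$radius_mm <- v$radius_mm * g
    v$species_mix <- v$species_mix * g
    v
  })
  snap <- make_phantom(vessels, phantom$grid_shape, phantom$voxel_size_mm,
                       phantom$background, phantom$sound_speed_mps,
                       phantom$seed)
  attr(snap, "scale") <- g
  snap
}

#' Total chromophore amount in a phantom
#'
#' Sum of concentration times voxel volume, in mol (with concentrations in
#' mol/L and voxel volume converted from mm^3 to L).
#'
#' @param phantom a `digital_phantom`.
#' @param species species name.
#' @return scalar amount, mol.
#' @export
phantom_amount <- function(phantom, species = "ICG") {
  sum(phantom$conc[[species]]) * phantom$voxel_size_mm^3 * 1e-6
}

#' Write a phantom to NIfTI files plus a YAML scene description
#'
#' One NIfTI per species grid and one for the scatterer amplitudes, with mm
#' voxel spacing in the header, plus `scene.yaml` describing the vessels,
#' background, and seed.
#'
#' @param phantom a `digital_phantom`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_phantom <- function(phantom, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  as_nifti_mm <- function(arr) {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- rep(phantom$voxel_size_mm, 3)
    img
  }
  for (s in names(phantom$conc)) {
    p <- file.path(dir, paste0("conc_", s, ".nii.gz"))
    RNifti::writeNifti(as_nifti_mm(phantom$conc[[s]]), p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "scatter_amp.nii.gz")
  RNifti::writeNifti(as_nifti_mm(phantom$scatter_amp), p)
  paths <- c(paths, p)
  scene <- list(
    grid_shape = as.integer(phantom$grid_shape),
    voxel_size_mm = phantom$voxel_size_mm,
    sound_speed_mps = phantom$sound_speed_mps,
    background = phantom$background,
    seed = phantom$seed,
    vessels = lapply(phantom$vessels, function(v) {
      list(species = v$species, radius_mm = v$radius_mm,
           so2 = if (is.na(v$so2)) NULL else v$so2,
           total_conc_M = sum(v$species_mix),
           pulsatile = v$pulsatile,
           centerline = apply(v$centerline, 1, as.list))
    }))
  yaml_path <- file.path(dir, "scene.yaml")
  yaml::write_yaml(scene, yaml_path)
  invisible(c(paths, yaml_path))
}
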