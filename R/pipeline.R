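#' Pipeline configuration
#'
#' Bundles everything one run needs: the scene (a `digital_phantom` or a
#' generator thereof), transducer and acquisition specs, unmixing species,
#' output directory, seed, and stage toggles.
#'
#' @param phantom a `digital_phantom`.
#' @param tx,acq specs; defaults are the package's device defaults.
#' @param species species to unmix.
#' @param out_dir output directory.
#' @param seed run seed (mandatory; funnels every stochastic stage).
#' @param stages character subset of
#'   `c("simulate", "recon", "unmix", "volume", "metrics")`.
#' @param spectra a `spectra_table`; default the shipped table.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(phantom, tx = transducer_spec(),
                            acq = acquisition_spec(), species = c("Hb", "HbO2", "ICG"),
                            out_dir = tempfile("tripai_run_"), seed = 1L,
                            stages = c("simulate", "recon", "unmix",
                                       "volume", "metrics"),
                            spectra = load_spectra()) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(phantom = phantom, tx = tx, acq = acq, species = species,
                 out_dir = out_dir, seed = as.integer(seed),
                 stages = stages, spectra = spectra),
            class = "pipeline_config")
}

stage_log <- function(manifest, stage, t0, outputs) {
  manifest$stages[[stage]] <- list(
    wall_s = round(as.numeric(Sys.time()) - t0, 3),
    outputs = as.list(outputs),
    md5 = as.list(unname(tools::md5sum(outputs))))
  manifest
}

#' Run the simulate -> recon -> unmix -> volume -> metrics pipeline
#'
#' Executes the enabled stages in order on one scene, persisting artifacts
#' under the configured output directory, and writes `manifest.json`
#' recording inputs, outputs, MD5 hashes, package version, and the seed, so
#' a rerun with the same config reproduces identical hashes. A stage
#' failure aborts with the stage name; artifacts of completed stages
#' remain on disk.
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (invisibly also written as JSON).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed,
                   version = as.character(utils::packageVersion("tripai")),
                   stages = list())
  acq <- config$acq
  acq$seed <- config$seed
  raw_path <- file.path(config$out_dir, "raw.rds")
  current_stage <- "none"
  tryCatch({
    if ("simulate" %in% config$stages) {
      current_stage <- "simulate"
      t0 <- as.numeric(Sys.time())
      frame <- simulate_frame(config$phantom, config$tx, acq, config$spectra)
      write_run(list(frame), raw_path, config$tx, acq)
      manifest <- stage_log(manifest, "simulate", t0, raw_path)
    }
    frames_dir <- file.path(config$out_dir, "frames")
    pa_imgs <- NULL
    us_img <- NULL
    if ("recon" %in% config$stages) {
      current_stage <- "recon"
      t0 <- as.numeric(Sys.time())
      if (!file.exists(raw_path)) stop("no raw container at ", raw_path)
      run <- read_run(raw_path)
      bundles <- frame_sequencer(run)
      dir.create(frames_dir, showWarnings = FALSE)
      outs <- character(0)
      grid <- image_grid()
      for (b in bundles) {
        pa_imgs <- lapply(b$pa, das_pa, grid = grid)
        us_img <- das_us(b$us, grid = grid)
        for (i in seq_along(pa_imgs)) {
          p <- file.path(frames_dir,
                         sprintf("pa_%dnm.tiff", round(b$wavelengths_nm[i])))
          outs <- c(outs, write_bscan(envelope_image(pa_imgs[[i]]), p))
        }
        p <- file.path(frames_dir, "us.tiff")
        outs <- c(outs, write_bscan(envelope_log(us_img), p))
      }
      manifest <- stage_log(manifest, "recon", t0, outs)
    }
    if ("unmix" %in% config$stages) {
      current_stage <- "unmix"
      t0 <- as.numeric(Sys.time())
      if (is.null(pa_imgs)) stop("unmix requires the recon stage outputs")
      stack <- spectral_stack(lapply(pa_imgs, envelope_image),
                              acq$wavelengths_nm)
      stack <- fluence_compensate(stack)
      M <- build_M(config$spectra, acq$wavelengths_nm, config$species)
      maps <- unmix(stack, M)
      if (all(c("Hb", "HbO2") %in% config$species)) maps <- so2_map(maps)
      up <- file.path(config$out_dir, "unmixed.tiff")
      outs <- write_unmixed(maps, up)
      manifest <- stage_log(manifest, "unmix", t0, outs)
      manifest$unmixed <- maps
    }
    if ("volume" %in% config$stages && !is.null(pa_imgs)) {
      current_stage <- "volume"
      t0 <- as.numeric(Sys.time())
      grid <- image_grid()
      lane <- scan_lane(list(pa_imgs[[length(pa_imgs)]]$pixels),
                        grid$x, grid$z, channel = "PA")
      vol <- stitch_mosaic(list(lane))
      vp <- file.path(config$out_dir, "volume.nii.gz")
      write_volume(vol, vp)
      manifest <- stage_log(manifest, "volume", t0, vp)
    }
    if ("metrics" %in% config$stages && !is.null(pa_imgs)) {
      current_stage <- "metrics"
      t0 <- as.numeric(Sys.time())
      env <- envelope_matrix(pa_imgs[[1]]$pixels)
      mx <- which(env == max(env), arr.ind = TRUE)[1, ]
      prof <- env[mx[1], ]
      metrics <- list(
        pa_peak_amplitude = max(env),
        pa_lateral_fwhm_mm = tryCatch(
          fwhm(prof, image_grid()$pixel_size_mm), error = function(e) NA))
      mp <- file.path(config$out_dir, "metrics.json")
      jsonlite::write_json(metrics, mp, auto_unbox = TRUE, digits = NA)
      manifest <- stage_log(manifest, "metrics", t0, mp)
    }
  }, error = function(e) {
    stop("pipeline stage '", current_stage, "' failed: ",
         conditionMessage(e), call. = FALSE)
  })
  mpath <- file.path(config$out_dir, "manifest.json")
  keep <- manifest[c("seed", "version", "stages")]
  jsonlite::write_json(keep, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Desk-scale fixture scenes
#'
#' Deterministic analogue scenes for testing and demos:
#' * `two_tube` — one blood tube (sO2 0.95) and one ICG tube at 3 mm depth
#'   under a scattering background (trimodal benchmark layout);
#' * `lymphatic_rat_toy` — an ICG lymphatic duct plus a node and a blood
#'   vessel, for unmixing and mosaic work;
#' * `pulsatile_arm_toy` — a pulsatile artery (84 bpm) plus a static vein,
#'   with a 200-frame 20 Hz dynamics spec.
#'
#' @param kind fixture name.
#' @param seed integer seed.
#' @param dir optional output directory; when given, writes scene YAML +
#'   NIfTI grids, a raw channel-data container, and a `checksums.json`.
#' @return list with `phantom`, `tx`, `acq`, and (pulsatile) `dynamics`;
#'   plus `paths` when `dir` is given.
#' @export
make_fixtures <- function(kind = c("two_tube", "lymphatic_rat_toy",
                                   "pulsatile_arm_toy"), seed = 1L,
                          dir = NULL) {
  kind <- match.arg(kind)
  tx <- transducer_spec()
  straight <- function(x, z, y = 0.05) rbind(c(x, y, z), c(x, y, z))
  if (kind == "two_tube") {
    acq <- acquisition_spec(wavelengths_nm = c(690, 720, 756, 796),
                            seed = seed)
    vessels <- list(
      vessel_spec(straight(-4, 3), 0.5, "blood", so2 = 0.95),
      vessel_spec(straight(4, 3), 0.5, "icg"))
    phantom <- make_phantom(vessels, grid_shape = c(200, 1, 100),
                            voxel_size_mm = 0.1, seed = seed)
    out <- list(phantom = phantom, tx = tx, acq = acq)
  } else if (kind == "lymphatic_rat_toy") {
    acq <- acquisition_spec(wavelengths_nm = c(690, 720, 756, 796),
                            seed = seed)
    vessels <- list(
      vessel_spec(rbind(c(-6, 0.05, 3), c(6, 0.05, 3.5)), 0.4, "icg"),
      vessel_spec(straight(7, 4), 1.0, "icg", total_conc_M = 2e-4),
      vessel_spec(straight(-2, 5), 0.6, "blood", so2 = 0.8))
    phantom <- make_phantom(vessels, grid_shape = c(200, 1, 100),
                            voxel_size_mm = 0.1, seed = seed)
    out <- list(phantom = phantom, tx = tx, acq = acq)
  } else {
    acq <- acquisition_spec(wavelengths_nm = c(866), seed = seed)
    dynamics <- dynamics_spec(heart_rate_bpm = 84, frame_rate_hz = 20,
                              n_frames = 200)
    vessels <- list(
      vessel_spec(straight(-3, 4), 0.8, "blood", so2 = 0.95,
                  pulsatile = TRUE),
      vessel_spec(straight(3, 3), 1.0, "blood", so2 = 0.7))
    phantom <- make_phantom(vessels, grid_shape = c(200, 1, 100),
                            voxel_size_mm = 0.1, seed = seed)
    out <- list(phantom = phantom, tx = tx, acq = acq, dynamics = dynamics)
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- write_phantom(out$phantom, dir)
    frame <- simulate_frame(out$phantom, out$tx, out$acq, load_spectra())
    raw <- file.path(dir, "raw.rds")
    write_run(list(frame), raw, out$tx, out$acq)
    paths <- c(paths, raw)
    cks <- file.path(dir, "checksums.json")
    jsonlite::write_json(as.list(tools::md5sum(paths)), cks,
                         auto_unbox = TRUE)
    out$paths <- c(paths, cks)
  }
  out
}
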