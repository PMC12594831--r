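#' Image grid for B-mode reconstruction
#'
#' Default 40 x 20 mm field of view (lateral x axial) at 0.1 mm isotropic
#' pixels, laterally centered on the array.
#'
#' @param x_span_mm,z_span_mm lateral and axial extents.
#' @param pixel_size_mm pixel size.
#' @param z0_mm first depth.
#' @return an `image_grid`: list with pixel center vectors `x`, `z`.
#' @export
image_grid <- function(x_span_mm = 40, z_span_mm = 20, pixel_size_mm = 0.1,
                       z0_mm = 0) {
  nx <- round(x_span_mm / pixel_size_mm)
  nz <- round(z_span_mm / pixel_size_mm)
  structure(list(
    x = (seq_len(nx) - (nx + 1) / 2) * pixel_size_mm,
    z = z0_mm + (seq_len(nz) - 0.5) * pixel_size_mm,
    pixel_size_mm = pixel_size_mm,
    extent_mm = c(x_span_mm, z_span_mm)),
    class = "image_grid")
}

new_bscan <- function(pixels, grid, modality, domain = "rf",
                      wavelength_nm = NULL, frame_index = NA_integer_,
                      dynamic_range_db = NULL, provenance = list()) {
  structure(list(pixels = pixels, extent_mm = grid$extent_mm,
                 pixel_size_mm = grid$pixel_size_mm, x_mm = grid$x,
                 z_mm = grid$z, modality = modality, domain = domain,
                 wavelength_nm = wavelength_nm, frame_index = frame_index,
                 dynamic_range_db = dynamic_range_db,
                 provenance = provenance),
            class = "bscan_image")
}

#' @export
print.bscan_image <- function(x, ...) {
  cat("bscan_image:", x$modality, x$domain,
      if (!is.null(x$wavelength_nm)) paste0("@", x$wavelength_nm, "nm") else "",
      "|", nrow(x$pixels), "z x", ncol(x$pixels), "x pixels |",
      paste(x$extent_mm, collapse = " x "), "mm\n")
  invisible(x)
}

#' Delay-and-sum reconstruction of photoacoustic channel data
#'
#' One-way time-delay beamforming: each pixel sums the element traces at
#' `t = dist(element, pixel) / c` with linear inter-sample interpolation,
#' dynamic-aperture apodization, and normalization by the recorded receive
#' gain (`10^(-gain_db/20)`), so images are gain-invariant. Pixels whose
#' delay falls outside the trace contribute zero and are counted in
#' provenance.
#'
#' @param channel a PA `channel_data`.
#' @param tx a [transducer_spec()] (defaults to the one in `channel`).
#' @param grid an [image_grid()].
#' @param fnum receive f-number for the dynamic aperture (`<= 0`: full
#'   aperture).
#' @param apodization `"hann"` or `"rect"`.
#' @param sound_speed_mps beamforming sound speed.
#' @return a `bscan_image` (linear RF, pre-envelope).
#' @export
das_pa <- function(channel, tx = channel$tx, grid = image_grid(),
                   fnum = 1.0, apodization = c("hann", "rect"),
                   sound_speed_mps = 1540) {
  if (channel$modality != "PA") stop("das_pa expects PA channel data")
  apodization <- match.arg(apodization)
  res <- cpp_das_pa(channel$traces, element_positions(tx),
                    channel$sampling_mhz * 1e6, channel$t0_s,
                    sound_speed_mps, grid$x, grid$z, fnum,
                    if (apodization == "hann") 1L else 0L)
  px <- res$image * 10^(-channel$gain_db / 20)
  new_bscan(px, grid, "PA", "rf", wavelength_nm = channel$wavelength_nm,
            provenance = list(n_out_of_range = res$n_out_of_range,
                              fnum = fnum, apodization = apodization))
}

#' Delay-and-sum reconstruction of steered line-beam ultrasound packets
#'
#' Per-packet two-way beamforming (virtual-source transmit delay plus
#' receive delay), then compounding of the steered-angle images: coherent
#' (RF summation before envelope, default) or incoherent (envelope
#' summation) behind a flag.
#'
#' @param packets list of US `channel_data` at distinct steering angles.
#' @param tx a [transducer_spec()].
#' @param grid an [image_grid()].
#' @param compounding `"coherent"` or `"incoherent"`.
#' @param fnum,apodization receive aperture controls as in [das_pa()].
#' @param line_halfwidth_mm half-width of each transmit line's lateral
#'   support during beamforming; the default approximates the focused
#'   beam's width at focus.
#' @param sound_speed_mps beamforming sound speed.
#' @return a `bscan_image` (linear RF for coherent compounding; envelope
#'   domain for incoherent).
#' @export
das_us <- function(packets, tx = NULL, grid = image_grid(),
                   compounding = c("coherent", "incoherent"), fnum = 1.0,
                   apodization = c("hann", "rect"), line_halfwidth_mm = 0.4,
                   sound_speed_mps = 1540) {
  if (inherits(packets, "channel_data")) packets <- list(packets)
  compounding <- match.arg(compounding)
  apodization <- match.arg(apodization)
  if (!length(packets)) stop("no packets supplied")
  fs <- vapply(packets, `[[`, numeric(1), "sampling_mhz")
  if (length(unique(fs)) != 1) stop("packets have mismatched sampling rates")
  if (is.null(tx)) tx <- packets[[1]]$tx
  ex <- element_positions(tx)
  imgs <- lapply(packets, function(p) {
    if (p$modality != "US") stop("das_us expects US channel data")
    res <- cpp_das_us(p$traces, ex, ex, p$steer_angle_deg * pi / 180,
                      p$focal_mm, p$sampling_mhz * 1e6, p$t0_s,
                      sound_speed_mps, grid$x, grid$z, fnum,
                      if (apodization == "hann") 1L else 0L,
                      line_halfwidth_mm)
    res$image * 10^(-p$gain_db / 20)
  })
  px <- if (compounding == "coherent") {
    Reduce(`+`, imgs)
  } else {
    Reduce(`+`, lapply(imgs, envelope_matrix))
  }
  new_bscan(px, grid, "US",
            domain = if (compounding == "coherent") "rf" else "env",
            provenance = list(compounding = compounding,
                              angles = vapply(packets, `[[`, numeric(1),
                                              "steer_angle_deg")))
}

# analytic-signal magnitude along z (columns) via FFT
envelope_matrix <- function(rf) {
  n <- nrow(rf)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  analytic <- stats::mvfft(stats::mvfft(rf) * h, inverse = TRUE) / n
  Mod(analytic)
}

#' Envelope detection and log compression
#'
#' Analytic-signal magnitude along depth (FFT Hilbert pair), then
#' `20*log10(env/max)` floored at `-dynamic_range_db`.
#'
#' @param rf a linear-RF `bscan_image`.
#' @param dynamic_range_db display dynamic range; defaults 40 dB for US,
#'   30 dB for PA.
#' @return a `bscan_image` in dB domain (floor recorded in
#'   `dynamic_range_db`).
#' @export
envelope_log <- function(rf, dynamic_range_db = NULL) {
  stopifnot(inherits(rf, "bscan_image"))
  if (rf$domain == "db") stop("image is already log-compressed")
  if (is.null(dynamic_range_db)) {
    dynamic_range_db <- if (rf$modality == "US") 40 else 30
  }
  env <- if (rf$domain == "env") rf$pixels else envelope_matrix(rf$pixels)
  m <- max(env)
  if (m == 0) {
    warning("all-zero image: maximum undefined, returning floor")
    db <- matrix(-dynamic_range_db, nrow(env), ncol(env))
  } else {
    db <- pmax(20 * log10(pmax(env / m, .Machine$double.xmin)),
               -dynamic_range_db)
  }
  out <- rf
  out$pixels <- db
  out$domain <- "db"
  out$dynamic_range_db <- dynamic_range_db
  out
}

#' Envelope (linear) image
#'
#' Convenience: analytic-signal magnitude without log compression.
#' @param rf a linear-RF `bscan_image`.
#' @return a `bscan_image` in envelope domain.
#' @export
envelope_image <- function(rf) {
  stopifnot(inherits(rf, "bscan_image"), rf$domain == "rf")
  out <- rf
  out$pixels <- envelope_matrix(rf$pixels)
  out$domain <- "env"
  out
}

#' Sequence raw frames into reconstruction-ready bundles
#'
#' Groups a raw container's events into spectral cycles, verifying that
#' every cycle carries the full wavelength set, that PA events precede the
#' US packets by the configured delay (recorded in the US `t0_s`), and that
#' all US packets of a frame share geometry. Returns the ordered list of
#' frame bundles.
#'
#' @param run a container from [read_run()]/[write_run()], or a list of
#'   `trimodal_frame`s.
#' @return list of `trimodal_frame` bundles (possibly empty).
#' @export
frame_sequencer <- function(run) {
  frames <- if (!is.null(run$frames)) run$frames else run
  if (!length(frames)) return(list())
  acq <- if (!is.null(run$acq)) run$acq else frames[[1]]$pa[[1]]$acq
  expected <- acq$wavelengths_nm
  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    got <- vapply(fr$pa, `[[`, numeric(1), "wavelength_nm")
    missing <- setdiff(expected, got)
    if (length(missing)) {
      stop("incomplete spectral cycle in frame ", i, ": missing ",
           paste(missing, "nm", collapse = ", "))
    }
    for (u in fr$us) {
      if (abs(u$event_offset_us - acq$pa_us_delay_us) > 1e-9) {
        stop("frame ", i, ": US packet does not follow PA by ",
             acq$pa_us_delay_us, " us")
      }
    }
  }
  frames
}

#' Write a B-scan as 32-bit TIFF with a JSON sidecar
#'
#' @param bscan a `bscan_image`.
#' @param path output TIFF path (sidecar gets `.json` appended).
#' @return invisibly, the paths written.
#' @export
write_bscan <- function(bscan, path) {
  px <- bscan$pixels
  # tiff float32 expects values; store raw values
  tiff::writeTIFF(px / max(abs(px), 1e-30) * 0.5 + 0.5, path,
                  bits.per.sample = 32L)
  meta <- list(extent_mm = bscan$extent_mm,
               pixel_size_mm = bscan$pixel_size_mm,
               modality = bscan$modality, domain = bscan$domain,
               wavelength_nm = bscan$wavelength_nm,
               dynamic_range_db = bscan$dynamic_range_db,
               scale = max(abs(px), 1e-30))
  jp <- paste0(path, ".json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(path, jp))
}
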