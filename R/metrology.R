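#' Electrical impedance spectrum of a resonator
#'
#' @param freqs_mhz ascending frequencies (>= 32 points spanning the
#'   resonance region).
#' @param magnitude_ohm positive impedance magnitudes.
#' @param phase_deg optional phase angles.
#' @return an `impedance_spectrum`.
#' @export
impedance_spectrum <- function(freqs_mhz, magnitude_ohm, phase_deg = NULL) {
  stopifnot(length(freqs_mhz) == length(magnitude_ohm),
            length(freqs_mhz) >= 32, all(magnitude_ohm > 0),
            !is.unsorted(freqs_mhz, strictly = TRUE))
  structure(list(freqs_mhz = freqs_mhz, magnitude_ohm = magnitude_ohm,
                 phase_deg = phase_deg),
            class = "impedance_spectrum")
}

# parabolic sub-sample refinement of an extremum at index i
parabolic_refine <- function(x, y, i) {
  if (i <= 1 || i >= length(x)) return(x[i])
  d <- (y[i - 1] - y[i + 1]) / (2 * (y[i - 1] - 2 * y[i] + y[i + 1]))
  if (!is.finite(d) || abs(d) > 1) d <- 0
  x[i] + d * (x[i + 1] - x[i])
}

#' Effective electromechanical coupling from an impedance spectrum
#'
#' Locates the impedance-magnitude minimum (resonance `f_r`) and the
#' following maximum (anti-resonance `f_a`), each refined parabolically,
#' and applies the standard resonance relation
#' `k_eff = sqrt(1 - (f_r / f_a)^2)`.
#'
#' @param spec an [impedance_spectrum()], or a list/data frame with
#'   `freqs_mhz` and `magnitude_ohm`.
#' @return list with `f_r_mhz`, `f_a_mhz`, `k_eff`.
#' @export
keff_from_impedance <- function(spec) {
  f <- spec$freqs_mhz
  m <- spec$magnitude_ohm
  i_min <- which.min(m)
  if (i_min >= length(m) - 1) stop("no impedance maximum found after the minimum")
  seg <- seq(i_min + 1, length(m))
  i_max <- seg[which.max(m[seg])]
  if (i_min <= 1 || i_max >= length(m)) {
    stop("resonance/anti-resonance pair not resolved inside the spectrum")
  }
  f_r <- parabolic_refine(f, m, i_min)
  f_a <- parabolic_refine(f, m, i_max)
  keff_from_frequencies(f_r, f_a)
}

#' @rdname keff_from_impedance
#' @param f_r_mhz,f_a_mhz resonance and anti-resonance frequencies, MHz.
#' @export
keff_from_frequencies <- function(f_r_mhz, f_a_mhz) {
  stopifnot(f_a_mhz >= f_r_mhz, f_r_mhz > 0)
  list(f_r_mhz = f_r_mhz, f_a_mhz = f_a_mhz,
       k_eff = sqrt(1 - (f_r_mhz / f_a_mhz)^2))
}

#' Pulse-echo waveform metrics
#'
#' Hann-windowed FFT amplitude spectrum; the -6 dB band edges are found by
#' linear interpolation around the spectral peak; center frequency is the
#' band midpoint and the fractional bandwidth is the band width over the
#' center. SNR is the peak absolute signal over the RMS of a pre-echo noise
#' window.
#'
#' @param waveform pulse-echo time series.
#' @param sampling_mhz sampling rate, MHz.
#' @param noise_window indices of a pre-echo noise segment; default the
#'   first 10% of samples.
#' @return a tibble with `center_freq_mhz`, `frac_bw_6db`, `snr_db`, and a
#'   `bw_limited` flag set when the -6 dB width is at the spectral
#'   resolution floor.
#' @export
pulse_echo_metrics <- function(waveform, sampling_mhz,
                               noise_window = NULL) {
  n <- length(waveform)
  stopifnot(n >= 16)
  w <- waveform * hann_window(n)
  nfft <- 2^ceiling(log2(n) + 2)        # zero-pad for band-edge resolution
  spec <- Mod(stats::fft(c(w, numeric(nfft - n))))[1:(nfft %/% 2)]
  freq <- (seq_len(nfft %/% 2) - 1) * sampling_mhz / nfft
  ipk <- which.max(spec)
  half <- spec[ipk] / 2                  # -6 dB on amplitude
  lo <- which(spec[1:ipk] < half)
  hi <- which(spec[ipk:length(spec)] < half)
  if (!length(lo) || !length(hi)) {
    stop("no -6 dB crossings: bandwidth undefined for this waveform")
  }
  il <- max(lo)
  f_low <- freq[il] + (half - spec[il]) / (spec[il + 1] - spec[il]) *
    (freq[il + 1] - freq[il])
  ih <- ipk + min(hi) - 1
  f_high <- freq[ih - 1] + (spec[ih - 1] - half) /
    (spec[ih - 1] - spec[ih]) * (freq[ih] - freq[ih - 1])
  fc <- (f_low + f_high) / 2
  bw <- (f_high - f_low) / fc
  df <- sampling_mhz / nfft
  if (is.null(noise_window)) noise_window <- seq_len(max(2, floor(n / 10)))
  noise_rms <- sqrt(mean(waveform[noise_window]^2))
  snr_db <- if (noise_rms > 0) {
    20 * log10(max(abs(waveform)) / noise_rms)
  } else {
    Inf
  }
  # a window-limited line (e.g. an unbroken tone) has a -6 dB width at the
  # Hann mainlobe scale fs/n, regardless of padding
  tibble::tibble(center_freq_mhz = fc, frac_bw_6db = bw, snr_db = snr_db,
                 bw_limited = (f_high - f_low) < 2.5 * sampling_mhz / n)
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

band_rms <- function(x, fs_mhz, band_mhz) {
  n <- length(x)
  X <- stats::fft(x)
  freq <- (seq_len(n) - 1) / n * fs_mhz
  freq <- pmin(freq, fs_mhz - freq)      # two-sided
  keep <- freq >= band_mhz[1] & freq <= band_mhz[2]
  sqrt(sum(Mod(X[keep])^2)) / n            # Parseval; both sidebands kept
}

#' Inter-element crosstalk in dB
#'
#' `20*log10(band-limited RMS of neighbor / band-limited RMS of drive)`,
#' evaluated over a 1-9 MHz band by default, with a pass/fail report
#' against the conventional -30 dB ceiling.
#'
#' @param drive driven-element time series.
#' @param neighbors list of neighbor time series, in neighbor order.
#' @param sampling_mhz common sampling rate.
#' @param band_mhz analysis band (within Nyquist).
#' @param criterion_db acceptance ceiling.
#' @return tibble: `order`, `crosstalk_db`, `pass`.
#' @export
crosstalk_db <- function(drive, neighbors, sampling_mhz,
                         band_mhz = c(1, 9), criterion_db = -30) {
  if (band_mhz[2] > sampling_mhz / 2) stop("band exceeds Nyquist")
  if (!is.list(neighbors)) neighbors <- list(neighbors)
  d_rms <- band_rms(drive, sampling_mhz, band_mhz)
  if (d_rms == 0) stop("drive signal has zero band-limited RMS")
  ct <- vapply(neighbors, function(nb) {
    20 * log10(band_rms(nb, sampling_mhz, band_mhz) / d_rms)
  }, numeric(1))
  tibble::tibble(order = seq_along(ct), crosstalk_db = ct,
                 pass = ct <= criterion_db)
}

#' Full width at half maximum of a 1-D profile
#'
#' Linear-interpolated half-maximum crossings around the dominant peak.
#'
#' @param profile sampled profile with a single dominant peak.
#' @param spacing_mm sample spacing, mm.
#' @return width in mm.
#' @export
fwhm <- function(profile, spacing_mm = 1) {
  n <- length(profile)
  ipk <- which.max(profile)
  if (ipk == 1 || ipk == n) stop("peak at profile boundary: FWHM undefined")
  half <- profile[ipk] / 2
  below_l <- which(profile[1:ipk] < half)
  below_r <- which(profile[ipk:n] < half)
  if (!length(below_l) || !length(below_r)) {
    stop("profile does not fall below half maximum on both sides")
  }
  il <- max(below_l)
  xl <- il + (half - profile[il]) / (profile[il + 1] - profile[il])
  ir <- ipk + min(below_r) - 1
  xr <- (ir - 1) + (profile[ir - 1] - half) / (profile[ir - 1] - profile[ir])
  (xr - xl) * spacing_mm
}

#' Contrast-to-noise ratio between two regions of interest
#'
#' `CNR = |mu_t - mu_b| / sqrt(sd_t^2 + sd_b^2)` on linear-envelope pixels
#' (pooled-deviation denominator); `denominator = "background"` uses
#' `|mu_t - mu_b| / sd_b` instead.
#'
#' @param image a `bscan_image` (envelope/linear) or matrix.
#' @param roi_target,roi_background logical masks or index matrices, each
#'   selecting >= 25 disjoint pixels.
#' @param denominator `"pooled"` or `"background"`.
#' @return scalar CNR.
#' @export
cnr <- function(image, roi_target, roi_background,
                denominator = c("pooled", "background")) {
  denominator <- match.arg(denominator)
  px <- if (inherits(image, "bscan_image")) image$pixels else image
  tv <- px[roi_target]
  bv <- px[roi_background]
  if (length(tv) < 25 || length(bv) < 25) stop("ROIs need >= 25 pixels each")
  if (is.logical(roi_target) && is.logical(roi_background) &&
      any(roi_target & roi_background)) {
    stop("ROIs must be disjoint")
  }
  s2 <- if (denominator == "pooled") {
    stats::var(tv) + stats::var(bv)
  } else {
    stats::var(bv)
  }
  if (s2 == 0) stop("zero variance in ROIs: CNR undefined")
  abs(mean(tv) - mean(bv)) / sqrt(s2)
}

#' Pulsation spectrum of an ROI intensity series
#'
#' Linear detrend, Hann window, zero-padded FFT; the fundamental is the
#' largest non-DC spectral peak, and harmonics are local peaks at integer
#' multiples of the fundamental within the spectral resolution. A constant
#' series yields a flagged no-peak result rather than an error.
#'
#' @param series ROI mean intensity per frame (>= 64 frames).
#' @param frame_rate_hz frame rate (must exceed twice the expected
#'   fundamental).
#' @param max_harmonic highest harmonic order searched.
#' @return list with `fundamental_hz` (NA if none), `harmonics_hz`,
#'   `spectrum` (tibble: freq_hz, amplitude), `found` flag.
#' @export
pulsation_spectrum <- function(series, frame_rate_hz, max_harmonic = 6) {
  n <- length(series)
  stopifnot(n >= 64, frame_rate_hz > 0)
  t <- seq_len(n)
  detr <- stats::residuals(stats::lm(series ~ t))
  if (max(abs(detr)) < 1e-12 * max(1, max(abs(series)))) {
    return(list(fundamental_hz = NA_real_, harmonics_hz = numeric(0),
                spectrum = tibble::tibble(freq_hz = numeric(0),
                                          amplitude = numeric(0)),
                found = FALSE))
  }
  w <- detr * hann_window(n)
  nfft <- 2^ceiling(log2(n) + 2)
  amp <- Mod(stats::fft(c(w, numeric(nfft - n))))[1:(nfft %/% 2)]
  freq <- (seq_len(nfft %/% 2) - 1) * frame_rate_hz / nfft
  res_hz <- frame_rate_hz / n             # pre-padding resolution
  nondc <- freq > 2 * res_hz
  ipk <- which(nondc)[which.max(amp[nondc])]
  f0 <- parabolic_refine(freq, amp, ipk)
  # local peaks
  is_peak <- c(FALSE, diff(sign(diff(amp))) < 0, FALSE)
  peak_freqs <- freq[is_peak]
  peak_amps <- amp[is_peak]
  harmonics <- numeric(0)
  for (h in 2:max_harmonic) {
    cand <- which(abs(peak_freqs - h * f0) <= res_hz)
    if (length(cand)) {
      harmonics <- c(harmonics, peak_freqs[cand[which.max(peak_amps[cand])]])
    }
  }
  list(fundamental_hz = f0, harmonics_hz = harmonics,
       spectrum = tibble::tibble(freq_hz = freq, amplitude = amp),
       found = TRUE)
}

#' Signal fold change between pre- and post-injection ROI means
#'
#' @param pre_roi_mean pre-injection ROI mean (> 0).
#' @param post_roi_mean post-injection ROI mean.
#' @return ratio `post / pre`.
#' @export
fold_change <- function(pre_roi_mean, post_roi_mean) {
  if (pre_roi_mean <= 0) stop("pre-injection ROI mean must be positive")
  post_roi_mean / pre_roi_mean
}
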