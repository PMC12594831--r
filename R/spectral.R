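#' Co-registered multispectral PA image stack
#'
#' @param images list of `bscan_image`s (linear amplitude) or matrices
#'   `[z, x]`, one per wavelength, co-registered.
#' @param wavelengths_nm wavelengths, one per image, distinct.
#' @param z_mm depth coordinates (taken from the first `bscan_image` if
#'   available).
#' @return a `spectral_stack` (array `[wavelength, z, x]`, `compensated`
#'   flag FALSE).
#' @export
spectral_stack <- function(images, wavelengths_nm, z_mm = NULL) {
  if (length(images) != length(wavelengths_nm)) {
    stop("one image per wavelength required")
  }
  if (anyDuplicated(wavelengths_nm)) stop("wavelengths must be distinct")
  mats <- lapply(images, function(im) {
    if (inherits(im, "bscan_image")) im$pixels else im
  })
  dims <- lapply(mats, dim)
  if (length(unique(dims)) != 1) stop("images must share shape")
  if (is.null(z_mm) && inherits(images[[1]], "bscan_image")) {
    z_mm <- images[[1]]$z_mm
  }
  if (is.null(z_mm)) z_mm <- seq_len(nrow(mats[[1]]))
  arr <- array(0, dim = c(length(mats), nrow(mats[[1]]), ncol(mats[[1]])))
  for (i in seq_along(mats)) arr[i, , ] <- mats[[i]]
  structure(list(images = arr, wavelengths_nm = wavelengths_nm,
                 z_mm = z_mm, compensated = FALSE, fit_log = NULL),
            class = "spectral_stack")
}

# fit b(z) ~ A * exp(-k z) by log-linear least squares on positive rows
fit_exp_decay <- function(z, b) {
  ok <- is.finite(b) & b > 0
  if (sum(ok) < 3) return(NULL)
  fit <- stats::lm(log(b[ok]) ~ z[ok])
  k <- -unname(stats::coef(fit)[2])
  list(A = exp(unname(stats::coef(fit)[1])), k = k)
}

#' Depth-wise fluence compensation
#'
#' For each wavelength, the background level at each depth is estimated as
#' a low percentile (default 20th) of the non-object pixel amplitudes in
#' that row; a single-exponential decay is fit to the background-versus-
#' depth profile and every row is divided by the fitted curve normalized to
#' 1 at z = 0. Compensation flattens the depth-dependent illumination decay
#' so that spectral unmixing sees fluence-free amplitudes. Rows with fewer
#' than 8 background pixels fall back to the global fit with a warning.
#'
#' @param stack an uncompensated `spectral_stack` of linear amplitudes.
#' @param object_mask optional logical matrix `[z, x]`, TRUE on object
#'   pixels to exclude from background estimation.
#' @param bg_percentile background percentile in (0, 1).
#' @return the compensated `spectral_stack`; per-wavelength fit parameters
#'   in `$fit_log`.
#' @export
fluence_compensate <- function(stack, object_mask = NULL,
                               bg_percentile = 0.2) {
  stopifnot(inherits(stack, "spectral_stack"))
  if (stack$compensated) stop("stack is already compensated")
  if (all(stack$images == 0)) stop("all-zero stack: cannot compensate")
  nz <- dim(stack$images)[2]
  nx <- dim(stack$images)[3]
  z <- stack$z_mm
  fit_log <- list()
  for (i in seq_along(stack$wavelengths_nm)) {
    im <- abs(stack$images[i, , ])
    bg_ok <- if (is.null(object_mask)) {
      matrix(TRUE, nz, nx)
    } else {
      !object_mask
    }
    b <- vapply(seq_len(nz), function(r) {
      px <- im[r, bg_ok[r, ]]
      if (length(px) >= 8) stats::quantile(px, bg_percentile, names = FALSE)
      else NA_real_
    }, numeric(1))
    n_short <- sum(is.na(b))
    if (n_short > 0) {
      warning(n_short, " depth row(s) had < 8 background pixels; ",
              "using the global fit for them")
    }
    fit <- fit_exp_decay(z, b)
    if (is.null(fit)) {
      # degenerate background: global fallback on the whole image
      ball <- vapply(seq_len(nz), function(r) mean(im[r, ]), numeric(1))
      fit <- fit_exp_decay(z, ball)
      if (is.null(fit)) stop("cannot fit a fluence decay curve")
    }
    curve <- exp(-fit$k * (z - z[1]))   # normalized to 1 at the first depth
    stack$images[i, , ] <- stack$images[i, , ] / curve
    fit_log[[i]] <- list(wavelength_nm = stack$wavelengths_nm[i],
                         k_per_mm = fit$k, n_fallback_rows = n_short)
  }
  stack$compensated <- TRUE
  stack$fit_log <- fit_log
  stack
}

#' Pseudo-inverse spectral unmixing
#'
#' Per pixel, concentrations solve the unconstrained least-squares problem
#' `[C_1 ... C_n] = [PA_1 ... PA_k] . M^T . (M M^T)^-1`, where row n of `M`
#' is species n's normalized absorption spectrum over the k acquisition
#' wavelengths. Negative concentrations are retained as diagnostics; they
#' are clamped only when computing sO2 or for display.
#'
#' @param stack a compensated `spectral_stack`.
#' @param M spectral matrix from [build_M()]; columns must match the stack
#'   wavelengths.
#' @param require_compensated refuse uncompensated stacks (default TRUE).
#' @return an `unmixed_maps`: per-species concentration images, `so2` unset.
#' @export
unmix <- function(stack, M, require_compensated = TRUE) {
  stopifnot(inherits(stack, "spectral_stack"))
  if (require_compensated && !stack$compensated) {
    stop("stack must be fluence-compensated before unmixing")
  }
  k <- ncol(M)
  if (k != length(stack$wavelengths_nm)) {
    stop("M has ", k, " wavelength columns but the stack has ",
         length(stack$wavelengths_nm))
  }
  MMt <- M %*% t(M)
  if (rcond(MMt) < 1e-12) stop("M * M^T is numerically singular")
  pinv <- t(M) %*% solve(MMt)             # k x n
  dims <- dim(stack$images)
  PA <- matrix(stack$images, nrow = dims[1])       # k x (z*x)
  C <- t(pinv) %*% PA                              # n x (z*x)
  conc <- lapply(seq_len(nrow(M)), function(i) {
    matrix(C[i, ], dims[2], dims[3])
  })
  names(conc) <- rownames(M)
  structure(list(conc = conc, so2 = NULL, so2_mask = NULL,
                 threshold_used = NULL, z_mm = stack$z_mm,
                 wavelengths_nm = stack$wavelengths_nm),
            class = "unmixed_maps")
}

#' Oxygen-saturation map
#'
#' `sO2 = m_HbO2 / (m_HbO2 + m_Hb)` with negative concentrations clamped to
#' zero before the ratio. The map is defined only where the total
#' hemoglobin signal exceeds a threshold (default 5% of the 99th-percentile
#' total amplitude); elsewhere it is masked (NA).
#'
#' @param maps an `unmixed_maps` containing Hb and HbO2.
#' @param total_hb_threshold absolute threshold on `m_Hb + m_HbO2`; `NULL`
#'   for the default rule.
#' @return `maps` with `so2`, `so2_mask`, and `threshold_used` filled.
#' @export
so2_map <- function(maps, total_hb_threshold = NULL) {
  stopifnot(inherits(maps, "unmixed_maps"))
  if (!all(c("Hb", "HbO2") %in% names(maps$conc))) {
    stop("unmixed maps must contain Hb and HbO2")
  }
  hb <- pmax(maps$conc$Hb, 0)
  hbo2 <- pmax(maps$conc$HbO2, 0)
  total <- hb + hbo2
  if (is.null(total_hb_threshold)) {
    total_hb_threshold <- 0.05 * stats::quantile(total, 0.99, names = FALSE)
  }
  mask <- total >= total_hb_threshold & total > 0
  so2 <- matrix(NA_real_, nrow(hb), ncol(hb))
  so2[mask] <- hbo2[mask] / total[mask]
  maps$so2 <- so2
  maps$so2_mask <- mask
  maps$threshold_used <- total_hb_threshold
  maps
}

#' @export
print.unmixed_maps <- function(x, ...) {
  cat("unmixed_maps:", paste(names(x$conc), collapse = ", "),
      "|", nrow(x$conc[[1]]), "z x", ncol(x$conc[[1]]), "x\n")
  if (!is.null(x$so2)) {
    cat(sprintf("  sO2 filled on %d px (threshold %.3g)\n",
                sum(x$so2_mask), x$threshold_used))
  }
  invisible(x)
}

#' Write unmixed maps as multi-page TIFF plus JSON sidecar
#'
#' @param maps an `unmixed_maps`.
#' @param path output TIFF path.
#' @return invisibly, the paths written.
#' @export
write_unmixed <- function(maps, path) {
  pages <- maps$conc
  if (!is.null(maps$so2)) {
    so2 <- maps$so2
    so2[is.na(so2)] <- 0
    pages <- c(pages, list(sO2 = so2))
  }
  scales <- vapply(pages, function(p) max(abs(p), 1e-30), numeric(1))
  norm <- Map(function(p, s) pmin(pmax(p / s * 0.5 + 0.5, 0), 1),
              pages, scales)
  tiff::writeTIFF(norm, path, bits.per.sample = 32L)
  meta <- list(species = names(pages), scale = as.list(scales),
               threshold_used = maps$threshold_used,
               wavelengths_nm = maps$wavelengths_nm)
  jp <- paste0(path, ".json")
  jsonlite::write_json(meta, jp, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(c(path, jp))
}
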