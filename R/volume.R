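#' A single elevational scan lane
#'
#' An ordered stack of co-planar B-scan slices acquired while stepping the
#' probe elevationally (default 0.5 mm steps), at a lateral stage offset.
#'
#' @param slices list of matrices `[z, x]` (or `bscan_image`s), one per
#'   elevational position.
#' @param x_mm lateral pixel centers of the slices, mm (lane-local).
#' @param z_mm axial pixel centers, mm.
#' @param y_start_mm elevational position of the first slice.
#' @param y_step_mm elevational step (default 0.5).
#' @param lane_x_offset_mm stage lateral offset of this lane.
#' @param channel channel label (e.g. `"US"`, `"PA866"`, `"sO2"`).
#' @return a `scan_lane`.
#' @export
scan_lane <- function(slices, x_mm, z_mm, y_start_mm = 0, y_step_mm = 0.5,
                      lane_x_offset_mm = 0, channel = "PA") {
  mats <- lapply(slices, function(s) {
    if (inherits(s, "bscan_image")) s$pixels else s
  })
  if (length(unique(lapply(mats, dim))) != 1) {
    stop("slices must share geometry")
  }
  stopifnot(y_step_mm > 0, nrow(mats[[1]]) == length(z_mm),
            ncol(mats[[1]]) == length(x_mm))
  structure(list(slices = mats, x_mm = x_mm, z_mm = z_mm,
                 y_start_mm = y_start_mm, y_step_mm = y_step_mm,
                 lane_x_offset_mm = lane_x_offset_mm, channel = channel),
            class = "scan_lane")
}

lane_to_volume <- function(lane) {
  nz <- length(lane$z_mm)
  ny <- length(lane$slices)
  nx <- length(lane$x_mm)
  v <- array(0, dim = c(nz, ny, nx))
  for (j in seq_len(ny)) v[, j, ] <- lane$slices[[j]]
  v
}

#' Stitch overlapping scan lanes into a mosaic volume
#'
#' Lanes are registered by stage coordinates only (lateral offsets and
#' elevational starts). Overlapping voxels are combined by linear feathering
#' across the full overlap width — the weights of contributing lanes sum to
#' 1 everywhere — and non-overlap voxels are copied through.
#'
#' @param lanes list of [scan_lane()]s on co-planar z grids, overlapping by
#'   at least 1 mm laterally.
#' @param blend `"feather"` (linear cross-fade) or `"mean"`.
#' @return a `volume3d`: voxels `[z, y, x]` with coordinate vectors and the
#'   per-voxel total feather weight in `$weight_sum`.
#' @export
stitch_mosaic <- function(lanes, blend = c("feather", "mean")) {
  blend <- match.arg(blend)
  stopifnot(length(lanes) >= 1)
  z <- lanes[[1]]$z_mm
  step <- diff(lanes[[1]]$x_mm[1:2])
  for (l in lanes) {
    if (!isTRUE(all.equal(l$z_mm, z))) stop("lanes must share the z grid")
    if (!isTRUE(all.equal(diff(l$x_mm[1:2]), step))) {
      stop("lanes must share lateral pixel size")
    }
  }
  # global lateral grid (union of lane extents, on a common raster)
  gx_lo <- vapply(lanes, function(l) min(l$x_mm) + l$lane_x_offset_mm,
                  numeric(1))
  gx_hi <- vapply(lanes, function(l) max(l$x_mm) + l$lane_x_offset_mm,
                  numeric(1))
  ord <- order(gx_lo)
  lanes <- lanes[ord]
  gx_lo <- gx_lo[ord]; gx_hi <- gx_hi[ord]
  for (i in seq_len(length(lanes) - 1)) {
    if (gx_hi[i] - gx_lo[i + 1] < 1 - 1e-9) {
      stop("lanes ", i, " and ", i + 1, " overlap less than 1 mm ",
           "(offsets ", round(gx_lo[i], 2), " / ", round(gx_lo[i + 1], 2),
           " mm)")
    }
  }
  x_global <- seq(min(gx_lo), max(gx_hi) + step / 2, by = step)
  y_sets <- lapply(lanes, function(l) {
    l$y_start_mm + (seq_along(l$slices) - 1) * l$y_step_mm
  })
  y_global <- sort(unique(round(unlist(y_sets), 9)))
  nz <- length(z); ny <- length(y_global); nx <- length(x_global)
  acc <- array(0, dim = c(nz, ny, nx))
  wacc <- array(0, dim = c(nz, ny, nx))
  for (li in seq_along(lanes)) {
    l <- lanes[[li]]
    xg <- l$x_mm + l$lane_x_offset_mm
    ix <- round((xg - x_global[1]) / step) + 1
    # lateral feather ramp over the overlap with the previous/next lane
    w <- rep(1, length(xg))
    if (li > 1) {
      ov <- gx_hi[li - 1] - gx_lo[li]
      if (blend == "feather" && ov > 0) {
        ramp_in <- xg <= gx_lo[li] + ov
        w[ramp_in] <- (xg[ramp_in] - gx_lo[li]) / ov
      }
    }
    if (li < length(lanes)) {
      ov <- gx_hi[li] - gx_lo[li + 1]
      if (blend == "feather" && ov > 0) {
        ramp_out <- xg >= gx_hi[li] - ov
        w <- pmin(w, ifelse(ramp_out, (gx_hi[li] - xg) / ov, 1))
      }
    }
    for (j in seq_along(l$slices)) {
      iy <- which.min(abs(y_global - y_sets[[li]][j]))
      acc[, iy, ix] <- acc[, iy, ix] +
        sweep(l$slices[[j]], 2, w, `*`)
      wacc[, iy, ix] <- wacc[, iy, ix] + rep(w, each = nz)
    }
  }
  vox <- acc
  pos <- wacc > 0
  vox[pos] <- acc[pos] / wacc[pos]
  # feathered weights already sum to ~1 in overlaps; division also covers
  # the "mean" blend and y-edge cases
  structure(list(voxels = vox, z_mm = z, y_mm = y_global, x_mm = x_global,
                 extent_mm = c(diff(range(x_global)) + step,
                               diff(range(y_global)) +
                                 lanes[[1]]$y_step_mm,
                               diff(range(z)) + diff(z[1:2])),
                 channel = lanes[[1]]$channel, weight_sum = wacc),
            class = "volume3d")
}

#' @export
print.volume3d <- function(x, ...) {
  cat("volume3d:", x$channel, "|",
      paste(dim(x$voxels), collapse = " x "), "(z y x) |",
      paste(round(x$extent_mm, 1), collapse = " x "), "mm\n")
  invisible(x)
}

#' Maximum amplitude projection
#'
#' `pixel(x, y) = max_z |voxel|`.
#'
#' @param volume a `volume3d` (or a bare `[z, y, x]` array).
#' @return matrix `[y, x]` MAP image.
#' @export
map_projection <- function(volume) {
  v <- if (inherits(volume, "volume3d")) volume$voxels else volume
  if (!length(v)) stop("empty volume")
  apply(abs(v), c(2, 3), max)
}

#' Depth-encoded maximum amplitude projection
#'
#' Hue encodes the argmax depth of each (x, y) column, mapped linearly over
#' `z_range_mm` on a fixed blue-to-red HSV ramp (shallow = blue, deep = red,
#' hue monotone in depth); value encodes the normalized MAP amplitude.
#' Empty columns are transparent (alpha 0).
#'
#' @param volume a `volume3d`.
#' @param z_range_mm encoded depth range, default 0-10 mm.
#' @return array `[y, x, 4]` RGBA in [0, 1]; attribute `"colorbar"` maps
#'   depths to hues.
#' @export
depth_encode <- function(volume, z_range_mm = c(0, 10)) {
  v <- abs(if (inherits(volume, "volume3d")) volume$voxels else volume)
  z <- if (inherits(volume, "volume3d")) volume$z_mm else seq_len(dim(v)[1])
  if (z_range_mm[2] > max(z) + diff(z[1:2])) {
    stop("z_range exceeds the volume extent")
  }
  map <- apply(v, c(2, 3), max)
  arg <- apply(v, c(2, 3), which.max)
  depth <- matrix(z[arg], nrow(arg), ncol(arg))
  frac <- pmin(pmax((depth - z_range_mm[1]) /
                      diff(z_range_mm), 0), 1)
  hue <- 2 / 3 * (1 - frac)          # 2/3 (blue) at shallow -> 0 (red) deep
  val <- map / max(map, 1e-30)
  rgba <- array(0, dim = c(nrow(map), ncol(map), 4))
  col <- grDevices::hsv(h = as.vector(hue), s = 1, v = pmin(as.vector(val), 1))
  rgbm <- grDevices::col2rgb(col) / 255
  rgba[, , 1] <- matrix(rgbm[1, ], nrow(map))
  rgba[, , 2] <- matrix(rgbm[2, ], nrow(map))
  rgba[, , 3] <- matrix(rgbm[3, ], nrow(map))
  rgba[, , 4] <- (map > 0) * 1
  zz <- seq(z_range_mm[1], z_range_mm[2], length.out = 32)
  attr(rgba, "colorbar") <- data.frame(
    depth_mm = zz,
    hue = 2 / 3 * (1 - (zz - z_range_mm[1]) / diff(z_range_mm)))
  rgba
}

#' Overlay a PA (or unmixed-species) layer on a US background
#'
#' US rendered grayscale; the PA layer is alpha-blended in a fixed species
#' color (ICG green, Hb red, HbO2/generic PA hot orange) wherever it exceeds
#' the threshold.
#'
#' @param us a `bscan_image` (dB domain preferred) or matrix.
#' @param pa a co-registered `bscan_image`/matrix (linear amplitude).
#' @param threshold linear-amplitude threshold relative to the PA maximum
#'   (0-1).
#' @param alpha blend opacity in [0, 1].
#' @param species color key: `"ICG"`, `"Hb"`, `"HbO2"`, or `"PA"`.
#' @return array `[z, x, 3]` RGB in [0, 1].
#' @export
overlay <- function(us, pa, threshold = 0.2, alpha = 0.7, species = "PA") {
  usm <- if (inherits(us, "bscan_image")) us$pixels else us
  pam <- if (inherits(pa, "bscan_image")) pa$pixels else pa
  if (!all(dim(usm) == dim(pam))) {
    stop("overlay requires co-registered geometry (shape mismatch)")
  }
  gray <- (usm - min(usm)) / max(diff(range(usm)), 1e-30)
  pan <- abs(pam) / max(abs(pam), 1e-30)
  tint <- switch(species,
                 ICG = c(0, 1, 0), Hb = c(1, 0, 0),
                 HbO2 = c(1, 0.3, 0), c(1, 0.5, 0))
  a <- alpha * (pan >= threshold)
  out <- array(0, dim = c(nrow(usm), ncol(usm), 3))
  for (ch in 1:3) {
    out[, , ch] <- gray * (1 - a) + tint[ch] * pan * a
  }
  out
}

#' Write a volume as NIfTI with mm spacings
#'
#' @param volume a `volume3d`.
#' @param path output `.nii` / `.nii.gz` path.
#' @return invisibly, `path`.
#' @export
write_volume <- function(volume, path) {
  dz <- diff(volume$z_mm[1:2])
  dy <- if (length(volume$y_mm) > 1) diff(volume$y_mm[1:2]) else 1
  dx <- diff(volume$x_mm[1:2])
  img <- RNifti::asNifti(volume$voxels)
  RNifti::pixdim(img) <- c(dz, dy, dx)
  RNifti::writeNifti(img, path)
  invisible(path)
}
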