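# Locally orthogonal resampling. For each centerline position a local
# orthonormal frame (e_x', e_y', e_z') is built with e_z' along the bone
# axis; cross-sections are then sampled in the (x', y') plane, which makes
# thickness measurements independent of how the specimen was oriented in
# the scanner. Only local straightness of the bone is assumed.

#' Moving-average smoothing of a centerline
#'
#' Smooths the per-slice centers with a centered moving average (window
#' shrinks symmetrically near the ends), suppressing the pixel-quantization
#' jitter of per-slice centroids before tangents are taken.
#'
#' @param centerline data frame with columns `slice`, `x`, `y`.
#' @param window full window length in slices (odd; default 5).
#' @return data frame of the same shape with smoothed `x`, `y`.
#' @export
smooth_centerline <- function(centerline, window = 5L) {
  n <- nrow(centerline)
  h <- as.integer(window) %/% 2L
  sm <- function(v) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      w <- min(h, i - 1L, n - i)
      out[i] <- mean(v[(i - w):(i + w)])
    }
    out
  }
  data.frame(slice = centerline$slice, x = sm(centerline$x), y = sm(centerline$y))
}

#' Local tangent direction of the centerline
#'
#' Symmetric finite difference with half-window `w`:
#' `e_z' = normalize((x[i+w] - x[i-w], y[i+w] - y[i-w], 2 w))`,
#' clamped to one-sided differences at the centerline ends. Apply to a
#' smoothed centerline (see [smooth_centerline()]).
#'
#' @param centerline data frame with `x`, `y` per consecutive slice.
#' @param i index into the centerline (row).
#' @param w half-window in slices.
#' @return unit 3-vector `e_z'` in scanner coordinates.
#' @export
local_tangent <- function(centerline, i, w = 5L) {
  n <- nrow(centerline)
  check(n >= 2L, "local_tangent: centerline must have at least 2 points")
  lo <- max(1L, i - w); hi <- min(n, i + w)
  v <- c(centerline$x[hi] - centerline$x[lo],
         centerline$y[hi] - centerline$y[lo],
         hi - lo)
  v / vnorm(v)
}

#' Build the local orthonormal frame for a tangent
#'
#' The in-plane basis vector `e_y'` is the normalized rotation axis between
#' the scanner axis `e_z` and the bone tangent `e_z'` (their cross product);
#' `e_x'` completes the right-handed basis as `e_y' x e_z'`. When the
#' tangent is (numerically) parallel to the scanner axis the rotation axis
#' is undefined and the canonical identity frame is returned.
#'
#' The forward matrix maps scanner coordinates to bone coordinates
#' (`b = forward %*% s`); `inverse` is its transpose.
#'
#' @param ez unit tangent vector `e_z'`.
#' @param origin optional frame origin `(x, y, z)` in voxel coordinates.
#' @return object of class `local_frame`: list with `origin`, `basis` (3x3,
#'   rows `e_x'`, `e_y'`, `e_z'`), `forward`, `inverse`.
#' @export
build_frame <- function(ez, origin = c(0, 0, 0)) {
  check(abs(vnorm(ez) - 1) < 1e-8, "build_frame: tangent must be unit norm")
  ax <- cross3(c(0, 0, 1), ez)
  n <- vnorm(ax)
  if (n < 1e-8) {
    basis <- diag(3)
  } else {
    ey <- ax / n
    ex <- cross3(ey, ez)
    ex <- ex / vnorm(ex)
    basis <- rbind(ex, ey, ez, deparse.level = 0)
  }
  structure(list(origin = origin, basis = basis,
                 forward = basis, inverse = t(basis)),
            class = "local_frame")
}

#' Resample one slice orthogonal to the bone axis
#'
#' Samples the volume on a square grid in the frame's (x', y') plane
#' centered on the frame origin: output pixel (u, v) reads the volume at
#' `origin + u e_x' + v e_y'` by trilinear interpolation. Samples falling
#' outside the volume are background (0). For binary masks the 0/1 field is
#' interpolated trilinearly, which preserves sub-pixel boundary information;
#' threshold at 0.5 for a hard mask.
#'
#' @param volume numeric or logical 3D array.
#' @param frame a [build_frame()] whose `origin` lies inside the volume.
#' @param half_extent half side length of the sampling grid (pixels).
#' @param spacing sample spacing in voxel units (default 1, i.e. the
#'   stack's own resolution).
#' @param binary if `TRUE`, threshold the interpolated field at 0.5.
#' @return numeric (or logical, when `binary`) square matrix.
#' @export
resample_orthogonal <- function(volume, frame, half_extent, spacing = 1,
                                binary = FALSE) {
  d <- dim(volume)
  o <- frame$origin
  check(all(o >= 1) && all(o <= d),
        "resample_orthogonal: frame origin outside volume")
  if (is.logical(volume)) volume <- volume + 0
  u <- seq(-half_extent, half_extent, by = spacing)
  n <- length(u)
  U <- matrix(u, n, n); V <- matrix(u, n, n, byrow = TRUE)
  ex <- frame$basis[1, ]; ey <- frame$basis[2, ]
  px <- o[1] + U * ex[1] + V * ey[1]
  py <- o[2] + U * ex[2] + V * ey[2]
  pz <- o[3] + U * ex[3] + V * ey[3]
  out <- matrix(trilinear(volume, as.vector(px), as.vector(py), as.vector(pz)),
                n, n)
  if (binary) out >= 0.5 else out
}

#' Orthogonal cross-sections along a tracked bone
#'
#' For every centerline position: smooth the centerline, take the local
#' tangent, build the frame at the (smoothed) center, and resample the
#' given volume orthogonally. The longitudinal coordinate `xi` of each
#' cross-section is the arc length along the smoothed centerline measured
#' from the metatarsophalangeal joint (mm); the stretch between the joint
#' and the first tracked slice is extrapolated along the local tangent.
#'
#' @param volume 3D array to resample (grayscale stack or binary mask).
#' @param track a [track_bone()] result (provides centerline, voxel size and
#'   the measurement range).
#' @param half_extent half side length of each cross-section (pixels);
#'   default 1.5x the equivalent radius of the largest tracked region.
#' @param tangent_halfwin half-window of the tangent finite difference.
#' @param smooth_window moving-average window for the centerline.
#' @return list with `slices` (list of matrices), `xi_mm` (numeric vector),
#'   `frames` (list of `local_frame`).
#' @export
orthogonal_sections <- function(volume, track, half_extent = NULL,
                                tangent_halfwin = 5L, smooth_window = 5L) {
  cl <- smooth_centerline(track$centerline, smooth_window)
  n <- nrow(cl)
  vox_mm <- track$voxel_size_um / 1000
  if (is.null(half_extent))
    half_extent <- ceiling(1.5 * sqrt(max(track$areas) / pi))
  # arc length along the smoothed centerline, in mm
  seg <- sqrt(diff(cl$x)^2 + diff(cl$y)^2 + diff(cl$slice)^2) * vox_mm
  t0 <- local_tangent(cl, 1L, tangent_halfwin)
  # distance from the joint to the first tracked slice, along the bone
  xi0 <- (cl$slice[1] - track$seed$joint_z) * vox_mm / t0[3]
  xi <- xi0 + c(0, cumsum(seg))
  slices <- vector("list", n)
  frames <- vector("list", n)
  for (i in seq_len(n)) {
    ez <- local_tangent(cl, i, tangent_halfwin)
    fr <- build_frame(ez, origin = c(cl$x[i], cl$y[i], cl$slice[i]))
    frames[[i]] <- fr
    slices[[i]] <- resample_orthogonal(volume, fr, half_extent)
  }
  list(slices = slices, xi_mm = xi, frames = frames,
       half_extent = half_extent)
}
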