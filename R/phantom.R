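# Synthetic tubular-bone phantoms with analytic ground truth.
#
# A phantom is a voxelized tube (bright cortical ring, darker marrow, dark
# background, optionally a second adjacent tube bridged by
# intermediate-intensity soft tissue), with linear inner/outer radius
# profiles along the bone, optional tilt or curvature of the axis,
# anti-aliased edges, Gaussian blur (PSF) and additive Gaussian noise.
# Because the geometry is analytic, every pipeline stage can be validated
# without external scan data: the true centerline, radii, cortical
# thickness gradient and cortical thickness index are all known exactly.

#' Phantom specification
#'
#' Geometry in physical units (mm, converted through `voxel_size_um`),
#' intensities in arbitrary grayscale units. Radius profiles are linear in
#' the longitudinal coordinate xi (mm above the joint):
#' `r(xi) = value_at_joint + slope * xi`.
#'
#' Intensity defaults emulate micro-CT of a paw: radiodense bone is
#' brightest, marrow and soft tissue intermediate, air/background darkest,
#' and the soft tissue lies roughly midway between background and bone so
#' that a global threshold merges adjacent bones across the bridging
#' tissue while texture segmentation separates them.
#'
#' @param slice_dims in-plane dimensions (pixels).
#' @param n_slices number of slices.
#' @param voxel_size_um isotropic voxel size, micrometers.
#' @param joint_z slice index of the (virtual) metatarsophalangeal joint.
#' @param bone_z first and last slice containing bone.
#' @param centerline list: `model` one of `"straight"`, `"tilted"`,
#'   `"curved"`; `x0`, `y0` axis position at the joint slice (pixels);
#'   `angle_deg`, `azimuth_deg` for tilt; `amplitude_px`, `period_slices`
#'   for curvature.
#' @param r_out_mm,r_in_mm numeric length-2: (value at joint, slope).
#' @param intensities named numeric: `background`, `soft_tissue`,
#'   `marrow`, `bone`, strictly increasing in that order.
#' @param noise_sigma additive Gaussian noise standard deviation.
#' @param blur_sigma Gaussian PSF standard deviation (pixels); 0 disables.
#' @param aa_subdiv anti-aliasing subdivisions per pixel axis (3 gives 3x3
#'   area sampling of region boundaries).
#' @param companion optional second tube: list with `offset_px`
#'   (length-2), `r_out_mm`, `r_in_mm`, `bridged` (logical),
#'   `bridge_pad_px`.
#' @param rng_seed seed for the noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(slice_dims = c(72L, 72L), n_slices = 146L,
                         voxel_size_um = 14.599, joint_z = 6L,
                         bone_z = c(2L, n_slices - 2L),
                         centerline = list(model = "straight", x0 = 36,
                                           y0 = 36, angle_deg = 0,
                                           azimuth_deg = 0,
                                           amplitude_px = 0,
                                           period_slices = 140),
                         r_out_mm = c(0.30, 0), r_in_mm = c(0.18, 0),
                         intensities = c(background = 20, soft_tissue = 110,
                                         marrow = 120, bone = 230),
                         noise_sigma = 10, blur_sigma = 0.7,
                         aa_subdiv = 3L, companion = NULL, rng_seed = 1L) {
  defaults <- list(model = "straight", x0 = slice_dims[1] / 2,
                   y0 = slice_dims[2] / 2, angle_deg = 0, azimuth_deg = 0,
                   amplitude_px = 0, period_slices = 140)
  centerline <- utils::modifyList(defaults, centerline)
  check(length(slice_dims) == 2L && all(slice_dims >= 8),
        "phantom_spec: slice_dims must be two in-plane sizes >= 8 px")
  check(is.numeric(voxel_size_um) && voxel_size_um > 0,
        "phantom_spec: voxel_size_um must be > 0")
  check(length(bone_z) == 2L && bone_z[1] >= 1 && bone_z[1] < bone_z[2] &&
          bone_z[2] <= n_slices,
        "phantom_spec: bone_z must be an increasing pair within n_slices")
  check(joint_z >= 1 && joint_z <= n_slices,
        "phantom_spec: joint_z must lie within the stack")
  check(aa_subdiv >= 1, "phantom_spec: aa_subdiv must be >= 1")
  check(noise_sigma >= 0 && blur_sigma >= 0,
        "phantom_spec: noise_sigma and blur_sigma must be >= 0")
  check(all(diff(intensities[c("background", "soft_tissue", "marrow",
                               "bone")]) > 0),
        "phantom_spec: intensities must satisfy background < soft_tissue < marrow < bone")
  spec <- structure(list(
    slice_dims = as.integer(slice_dims), n_slices = as.integer(n_slices),
    voxel_size_um = voxel_size_um, joint_z = as.integer(joint_z),
    bone_z = as.integer(bone_z), centerline = centerline,
    r_out_mm = r_out_mm, r_in_mm = r_in_mm, intensities = intensities,
    noise_sigma = noise_sigma, blur_sigma = blur_sigma,
    aa_subdiv = as.integer(aa_subdiv), companion = companion,
    rng_seed = as.integer(rng_seed)), class = "phantom_spec")
  vox_mm <- voxel_size_um / 1000
  xi_max <- (bone_z[2] - joint_z) * vox_mm / cos(centerline$angle_deg * pi / 180)
  xi_chk <- seq(-(joint_z - bone_z[1]) * vox_mm, xi_max, length.out = 64)
  rin <- r_in_mm[1] + r_in_mm[2] * xi_chk
  rout <- r_out_mm[1] + r_out_mm[2] * xi_chk
  check(all(rin > 0) && all(rout > rin),
        "phantom_spec: need 0 < r_in(xi) < r_out(xi) over the whole bone")
  spec
}

# axis point (pixels) and unit direction at slice z
phantom_axis <- function(spec, z) {
  cl <- spec$centerline
  dz <- z - spec$joint_z
  if (cl$model == "straight") {
    list(a = c(cl$x0, cl$y0, z), d = c(0, 0, 1))
  } else if (cl$model == "tilted") {
    al <- cl$angle_deg * pi / 180; be <- cl$azimuth_deg * pi / 180
    list(a = c(cl$x0 + tan(al) * cos(be) * dz,
               cl$y0 + tan(al) * sin(be) * dz, z),
         d = c(sin(al) * cos(be), sin(al) * sin(be), cos(al)))
  } else if (cl$model == "curved") {
    wv <- 2 * pi / cl$period_slices
    v <- c(cl$amplitude_px * wv * cos(wv * dz), 0, 1)
    list(a = c(cl$x0 + cl$amplitude_px * sin(wv * dz), cl$y0, z),
         d = v / vnorm(v))
  } else stop("phantom_axis: unknown centerline model")
}

#' Generate a phantom stack with its ground truth
#'
#' Voxelizes the tube(s): region boundaries are anti-aliased by
#' `aa_subdiv^2` sub-pixel area sampling, intensities assigned per region,
#' then Gaussian blur and seeded Gaussian noise are applied. The returned
#' truth (mask, centerline, radii, analytic CTG/CTI, bone coverage
#' fraction) is computed before any degradation and is never altered by
#' it; generation is deterministic for a given `rng_seed`.
#'
#' @param spec a [phantom_spec()].
#' @return list with `stack` (a [ct_stack()]), `truth` (list: `mask` all
#'   bone voxels at pixel-center resolution, `mask_primary` the seeded
#'   tube only, `coverage` the anti-aliased bone area fraction per voxel of
#'   the primary tube, `centerline` data frame of the true axis,
#'   `ctg_true`, `r_in_fn`, `r_out_fn`, `cti_true(xi_range)`), and `spec`.
#' @export
generate_phantom <- function(spec) {
  D <- spec$slice_dims; S <- spec$n_slices
  vox_mm <- spec$voxel_size_um / 1000
  rin_fn <- function(xi) spec$r_in_mm[1] + spec$r_in_mm[2] * xi
  rout_fn <- function(xi) spec$r_out_mm[1] + spec$r_out_mm[2] * xi
  comp <- spec$companion
  if (!is.null(comp)) {
    rin2_fn <- function(xi) comp$r_in_mm[1] + comp$r_in_mm[2] * xi
    rout2_fn <- function(xi) comp$r_out_mm[1] + comp$r_out_mm[2] * xi
    bridge_pad <- if (is.null(comp$bridge_pad_px)) 2 else comp$bridge_pad_px
  }

  # cumulative axis arc length (pixels) from the joint slice, per slice
  ax <- lapply(seq_len(S), function(z) phantom_axis(spec, z))
  axy <- t(vapply(ax, function(a) a$a, numeric(3)))
  seg <- sqrt(rowSums(diff(axy)^2))
  arc <- c(0, cumsum(seg))
  arc <- arc - arc[spec$joint_z]

  ints <- spec$intensities
  vol <- array(ints[["background"]], c(D[1], D[2], S))
  mask <- array(FALSE, c(D[1], D[2], S))
  mask1 <- array(FALSE, c(D[1], D[2], S))
  coverage <- array(0, c(D[1], D[2], S))

  offs <- (seq_len(spec$aa_subdiv) - (spec$aa_subdiv + 1) / 2) / spec$aa_subdiv
  gx <- rep(seq_len(D[1]), D[2])
  gy <- rep(seq_len(D[2]), each = D[1])

  # radial distance (px) to a tube axis and the longitudinal coord xi (mm)
  radial <- function(px, py, a, d, arc_z) {
    wx <- px - a[1]; wy <- py - a[2]
    t_ax <- wx * d[1] + wy * d[2]          # (p - a) . d with p_z = a_z
    rx <- wx - t_ax * d[1]; ry <- wy - t_ax * d[2]; rz <- -t_ax * d[3]
    list(r = sqrt(rx^2 + ry^2 + rz^2), xi = (arc_z + t_ax) * vox_mm)
  }

  for (z in spec$bone_z[1]:spec$bone_z[2]) {
    a <- ax[[z]]
    if (!is.null(comp)) {
      a2 <- list(a = a$a + c(comp$offset_px, 0), d = a$d)
      mid <- (a$a[1:2] + a2$a[1:2]) / 2
      seg_half <- vnorm(a2$a[1:2] - a$a[1:2]) / 2
      seg_dir <- (a2$a[1:2] - a$a[1:2]) / (2 * seg_half)
    }
    accI <- numeric(D[1] * D[2])
    accC <- numeric(D[1] * D[2])
    for (ox in offs) for (oy in offs) {
      p1 <- radial(gx + ox, gy + oy, a$a, a$d, arc[z])
      bone1 <- p1$r < rout_fn(p1$xi) / vox_mm & p1$r >= rin_fn(p1$xi) / vox_mm
      marrow1 <- p1$r < rin_fn(p1$xi) / vox_mm
      bone <- bone1; marrow <- marrow1; soft <- rep(FALSE, length(bone))
      if (!is.null(comp)) {
        p2 <- radial(gx + ox, gy + oy, a2$a, a2$d, arc[z])
        bone <- bone | (p2$r < rout2_fn(p2$xi) / vox_mm &
                        p2$r >= rin2_fn(p2$xi) / vox_mm)
        marrow <- marrow | p2$r < rin2_fn(p2$xi) / vox_mm
        if (isTRUE(comp$bridged)) {
          # soft-tissue capsule around the segment joining the two axes
          t_seg <- (gx + ox - mid[1]) * seg_dir[1] + (gy + oy - mid[2]) * seg_dir[2]
          t_seg <- pmin(pmax(t_seg, -seg_half), seg_half)
          qx <- mid[1] + t_seg * seg_dir[1]; qy <- mid[2] + t_seg * seg_dir[2]
          dd <- sqrt((gx + ox - qx)^2 + (gy + oy - qy)^2)
          rcap <- max(rout_fn(p1$xi[1]), rout2_fn(p2$xi[1])) / vox_mm + bridge_pad
          soft <- dd <= rcap
        }
      }
      val <- rep(ints[["background"]], length(bone))
      val[soft] <- ints[["soft_tissue"]]
      val[marrow] <- ints[["marrow"]]
      val[bone] <- ints[["bone"]]
      accI <- accI + val
      accC <- accC + bone1
    }
    vol[, , z] <- matrix(accI / spec$aa_subdiv^2, D[1], D[2])
    coverage[, , z] <- matrix(accC / spec$aa_subdiv^2, D[1], D[2])
    pc <- radial(gx, gy, a$a, a$d, arc[z])
    b1 <- pc$r < rout_fn(pc$xi) / vox_mm & pc$r >= rin_fn(pc$xi) / vox_mm
    mask1[, , z] <- matrix(b1, D[1], D[2])
    ball <- b1
    if (!is.null(comp)) {
      pc2 <- radial(gx, gy, a2$a, a2$d, arc[z])
      ball <- ball | (pc2$r < rout2_fn(pc2$xi) / vox_mm &
                      pc2$r >= rin2_fn(pc2$xi) / vox_mm)
    }
    mask[, , z] <- matrix(ball, D[1], D[2])
    # geometry containment check
    rmax <- rout_fn(pc$xi[1]) / vox_mm
    check(a$a[1] - rmax >= 1 && a$a[1] + rmax <= D[1] &&
          a$a[2] - rmax >= 1 && a$a[2] + rmax <= D[2],
          "generate_phantom: bone exits the volume at slice %d", z)
  }

  if (spec$blur_sigma > 0)
    for (z in seq_len(S))
      vol[, , z] <- as.matrix(EBImage::gblur(EBImage::Image(vol[, , z]),
                                             spec$blur_sigma))
  if (spec$noise_sigma > 0)
    vol <- vol + with_seed(spec$rng_seed,
                           array(stats::rnorm(length(vol), 0, spec$noise_sigma),
                                 dim(vol)))

  ctg_true <- unname(spec$r_out_mm[2] - spec$r_in_mm[2])
  cti_true <- function(xi_range) {
    f <- function(xi) 1 - rin_fn(xi) / rout_fn(xi)
    stats::integrate(f, xi_range[1], xi_range[2])$value / diff(xi_range)
  }
  list(
    stack = ct_stack(vol, spec$voxel_size_um),
    truth = list(mask = mask, mask_primary = mask1, coverage = coverage,
                 centerline = data.frame(slice = seq_len(S),
                                         x = axy[, 1], y = axy[, 2]),
                 arc_px = arc, ctg_true = ctg_true,
                 r_in_fn = rin_fn, r_out_fn = rout_fn, cti_true = cti_true),
    spec = spec
  )
}

#' Named phantom presets
#'
#' A fixed, reproducible battery of validation phantoms: a straight
#' constant-radius tube, tilted tubes (15 and 25 degrees), a curved tube,
#' tapered-cortex tubes whose true CTG spans the healthy-to-arthritic
#' range 0 to 0.015, and an adjacent-bones scenario where two tubes are
#' bridged by soft tissue (the failure mode of plain thresholding). Each
#' preset carries a fixed seed, a ready seed annotation and the
#' measurement range to use.
#'
#' @param presets character vector of preset names; default all.
#' @return named list; each element has `spec` ([phantom_spec()]), `seed`
#'   (a [seed_annotation()]) and `range_mm`.
#' @export
phantom_suite <- function(presets = c("straight_constant", "tilted15",
                                      "tilted25", "curved",
                                      "tapered_ctg0e-3", "tapered_ctg5e-3",
                                      "tapered_ctg10e-3", "tapered_ctg15e-3",
                                      "adjacent_bones_bridged")) {
  mk_long <- function(cl, dims, seed_xy, rng_seed, r_in = c(0.18, 0),
                      r_out = c(0.30, 0)) {
    spec <- phantom_spec(slice_dims = dims, centerline = cl,
                         r_in_mm = r_in, r_out_mm = r_out,
                         rng_seed = rng_seed)
    list(spec = spec,
         seed = seed_annotation(seed_slice = 100L, x = seed_xy[1],
                                y = seed_xy[2], joint_z = spec$joint_z),
         range_mm = c(0.75, 1.95))
  }
  all <- list(
    straight_constant = function() mk_long(
      list(model = "straight", x0 = 36, y0 = 36), c(72L, 72L),
      # seed point on the ring, between the perimeters
      c(36 + 0.24 / 0.014599, 36), 101L),
    tilted15 = function() mk_long(
      list(model = "tilted", x0 = 26, y0 = 36, angle_deg = 15), c(104L, 72L),
      c(26 + tan(15 * pi / 180) * 94 + 0.24 / 0.014599, 36), 102L),
    tilted25 = function() mk_long(
      list(model = "tilted", x0 = 24, y0 = 36, angle_deg = 25), c(128L, 72L),
      c(24 + tan(25 * pi / 180) * 94 + 0.24 / 0.014599, 36), 103L),
    curved = function() mk_long(
      list(model = "curved", x0 = 36, y0 = 36, amplitude_px = 4,
           period_slices = 280), c(80L, 72L),
      c(36 + 4 * sin(2 * pi * 94 / 280) + 0.24 / 0.014599, 36), 104L),
    `tapered_ctg0e-3` = function() mk_long(
      list(model = "straight", x0 = 36, y0 = 36), c(72L, 72L),
      c(36 + 0.24 / 0.014599, 36), 111L, r_in = c(0.18, 0)),
    `tapered_ctg5e-3` = function() mk_long(
      list(model = "straight", x0 = 36, y0 = 36), c(72L, 72L),
      c(36 + 0.24 / 0.014599, 36), 112L, r_in = c(0.18, -0.005)),
    `tapered_ctg10e-3` = function() mk_long(
      list(model = "straight", x0 = 36, y0 = 36), c(72L, 72L),
      c(36 + 0.24 / 0.014599, 36), 113L, r_in = c(0.18, -0.010)),
    `tapered_ctg15e-3` = function() mk_long(
      list(model = "straight", x0 = 36, y0 = 36), c(72L, 72L),
      c(36 + 0.24 / 0.014599, 36), 114L, r_in = c(0.18, -0.015)),
    adjacent_bones_bridged = function() {
      spec <- phantom_spec(
        slice_dims = c(92L, 72L), n_slices = 36L, joint_z = 6L,
        bone_z = c(2L, 34L),
        centerline = list(model = "straight", x0 = 26, y0 = 36),
        r_out_mm = c(0.25, 0), r_in_mm = c(0.15, 0),
        companion = list(offset_px = c(40, 0), r_out_mm = c(0.25, 0),
                         r_in_mm = c(0.15, 0), bridged = TRUE),
        rng_seed = 120L)
      list(spec = spec,
           seed = seed_annotation(seed_slice = 20L,
                                  x = 26 + 0.20 / 0.014599, y = 36,
                                  joint_z = 6L),
           range_mm = c(0.1, 0.4))
    }
  )
  check(all(presets %in% names(all)), "phantom_suite: unknown preset name")
  lapply(stats::setNames(presets, presets), function(p) all[[p]]())
}
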