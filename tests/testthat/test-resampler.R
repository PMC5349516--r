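# Local frames and orthogonal resampling.

test_that("local tangent matches known centerline geometry", {
  # vertical centerline: tangent is the scanner z axis
  cl <- data.frame(slice = 1:11, x = rep(5, 11), y = rep(7, 11))
  expect_equal(local_tangent(cl, 6, w = 3), c(0, 0, 1), tolerance = 1e-12)
  # 45-degree diagonal in x and y: direction (1, 1, 1)/sqrt(3)
  cl2 <- data.frame(slice = 1:11, x = 1:11, y = 1:11)
  expect_equal(local_tangent(cl2, 6, w = 3), c(1, 1, 1) / sqrt(3),
               tolerance = 1e-12)
  # one-sided clamping at the ends still normalizes correctly
  t1 <- local_tangent(cl2, 1, w = 5)
  expect_equal(t1, c(1, 1, 1) / sqrt(3), tolerance = 1e-12)
  expect_equal(sqrt(sum(t1^2)), 1, tolerance = 1e-12)
})

test_that("centerline smoothing preserves straight lines and endpoints", {
  cl <- data.frame(slice = 1:20, x = 2 * (1:20) + 3, y = rep(4, 20))
  sm <- smooth_centerline(cl, window = 5)
  expect_equal(sm$x, cl$x, tolerance = 1e-12)   # linear -> unchanged
  expect_equal(sm$y, cl$y, tolerance = 1e-12)
  # smoothing reduces jitter variance
  set.seed(3)
  cl2 <- data.frame(slice = 1:50, x = 10 + rnorm(50, sd = 0.5), y = rep(0, 50))
  sm2 <- smooth_centerline(cl2, window = 5)
  expect_lt(stats::var(sm2$x), stats::var(cl2$x))
})

test_that("frames from 100 random tangents are orthonormal right-handed", {
  set.seed(12)
  for (i in 1:100) {
    v <- rnorm(3)
    ez <- v / sqrt(sum(v^2))
    fr <- build_frame(ez)
    B <- fr$basis
    expect_lt(max(abs(B %*% t(B) - diag(3))), 1e-10)
    expect_lt(max(abs(fr$forward %*% fr$inverse - diag(3))), 1e-10)
    expect_lt(abs(det(B) - 1), 1e-10)
    expect_equal(unname(B[3, ]), ez, tolerance = 1e-12)
    # round trip scanner -> bone -> scanner
    p <- rnorm(3)
    expect_equal(as.vector(fr$inverse %*% (fr$forward %*% p)), p,
                 tolerance = 1e-10)
  }
})

test_that("a tangent parallel to the scanner axis yields the identity frame", {
  fr <- build_frame(c(0, 0, 1))
  expect_equal(fr$basis, diag(3), tolerance = 0)
  fr2 <- build_frame(c(1e-12, 0, sqrt(1 - 1e-24)))
  expect_equal(fr2$basis, diag(3), tolerance = 0)
  expect_error(build_frame(c(0, 0, 2)), "unit")
})

test_that("identity-frame resampling reproduces the slice", {
  set.seed(4)
  vol <- array(runif(21 * 21 * 9), c(21, 21, 9))
  fr <- build_frame(c(0, 0, 1), origin = c(11, 11, 5))
  out <- resample_orthogonal(vol, fr, half_extent = 6)
  expect_equal(out, vol[5:17, 5:17, 5], tolerance = 1e-12)
  # out-of-volume samples fill with background 0
  out2 <- resample_orthogonal(vol, fr, half_extent = 15)
  expect_equal(out2[1, 1], 0)
  expect_error(resample_orthogonal(vol, build_frame(c(0, 0, 1)), 3), "origin")
})

test_that("trilinear resampling is exact for a linear intensity field", {
  d <- c(20, 20, 20)
  vol <- array(0, d)
  for (z in 1:20) vol[, , z] <-
      outer(1:20, 1:20, function(x, y) 0.3 * x - 0.2 * y) + 0.5 * z
  v <- c(1, 0.5, 1.5); ez <- v / sqrt(sum(v^2))
  fr <- build_frame(ez, origin = c(10, 10, 10))
  out <- resample_orthogonal(vol, fr, half_extent = 3)
  # analytic value of the linear field at each sample point
  u <- -3:3
  ref <- matrix(0, 7, 7)
  for (a in 1:7) for (b in 1:7) {
    p <- fr$origin + u[a] * fr$basis[1, ] + u[b] * fr$basis[2, ]
    ref[a, b] <- 0.3 * p[1] - 0.2 * p[2] + 0.5 * p[3]
  }
  expect_equal(out, ref, tolerance = 1e-10)
})

test_that("orthogonal sections of a tilted tube are circular", {
  # a 20-degree tilted anti-aliased tube: in-plane sections are ellipses
  # (axis ratio 1/cos 20 ~ 1.064), orthogonal sections circles
  sp <- phantom_spec(
    slice_dims = c(80L, 48L), n_slices = 60L, joint_z = 4L,
    bone_z = c(2L, 58L),
    centerline = list(model = "tilted", x0 = 18, y0 = 24, angle_deg = 20),
    r_in_mm = c(0.10, 0), r_out_mm = c(0.17, 0),
    noise_sigma = 0, blur_sigma = 0, rng_seed = 77L)
  ph <- generate_phantom(sp)
  sd <- seed_annotation(30, 18 + tan(20 * pi / 180) * 26 + 0.15 / 0.014599,
                        24, 4)
  tr <- track_bone(ph$truth$mask, sd, sp$voxel_size_um, c(0.15, 0.65))
  os <- orthogonal_sections(ph$truth$coverage, tr)
  mid <- (length(os$slices) + 1) %/% 2
  pr_o <- perimeter_radii(os$slices[[mid]], n_theta = 72)
  ratio_o <- max(pr_o$r_out[pr_o$valid]) / min(pr_o$r_out[pr_o$valid])
  z <- tr$centerline$slice[mid]
  pr_i <- perimeter_radii(ph$truth$coverage[, , z], n_theta = 72)
  ratio_i <- max(pr_i$r_out[pr_i$valid]) / min(pr_i$r_out[pr_i$valid])
  expect_lt(ratio_o, 1.05)
  expect_gte(ratio_i, 1.06)
})

test_that("xi is arc length: tilted tube sections advance by 1/cos(angle)", {
  sp <- phantom_spec(
    slice_dims = c(80L, 48L), n_slices = 60L, joint_z = 4L,
    bone_z = c(2L, 58L),
    centerline = list(model = "tilted", x0 = 18, y0 = 24, angle_deg = 20),
    r_in_mm = c(0.10, 0), r_out_mm = c(0.17, 0),
    noise_sigma = 0, blur_sigma = 0, rng_seed = 77L)
  ph <- generate_phantom(sp)
  sd <- seed_annotation(30, 18 + tan(20 * pi / 180) * 26 + 0.15 / 0.014599,
                        24, 4)
  tr <- track_bone(ph$truth$mask, sd, sp$voxel_size_um, c(0.15, 0.65))
  os <- orthogonal_sections(ph$truth$mask, tr)
  step <- diff(os$xi_mm)
  vox_mm <- sp$voxel_size_um / 1000
  expect_equal(mean(step), vox_mm / cos(20 * pi / 180), tolerance = 0.01)
  expect_true(all(diff(os$xi_mm) > 0))
})
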