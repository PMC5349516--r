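# Perimeter radii, angular averaging, CTG fit and CTI.

test_that("annulus radii are recovered to sub-pixel accuracy on all rays", {
  img <- make_annulus(51, c(26, 26), r_in = 10, r_out = 20)
  pr <- perimeter_radii(img, n_theta = 25)
  expect_true(all(pr$valid))
  expect_true(all(abs(pr$r_in - 10) < 0.5))
  expect_true(all(abs(pr$r_out - 20) < 0.5))
})

test_that("a solid disc has no valid rays and an empty field errors", {
  img <- make_annulus(41, c(21, 21), r_in = 0, r_out = 12)
  pr <- perimeter_radii(img, n_theta = 25)
  expect_false(any(pr$valid))
  expect_error(perimeter_radii(matrix(0, 10, 10)), "empty")
})

test_that("a broken annulus invalidates exactly the gap directions", {
  img <- make_annulus(51, c(26, 26), r_in = 10, r_out = 20)
  # cut the ring open toward +x: rays near theta = 0 find no wall at all
  X <- matrix(seq_len(51) - 26, 51, 51)
  Y <- matrix(seq_len(51) - 26, 51, 51, byrow = TRUE)
  gap <- X > 0 & abs(Y) <= 2
  img[gap] <- 0
  pr <- perimeter_radii(img, n_theta = 24, center = c(26, 26))
  expect_false(pr$valid[1])                    # theta = 0 has no crossings
  expect_true(pr$valid[7])                     # theta = pi/2 intact
  expect_true(pr$valid[13])                    # theta = pi intact
  expect_gt(sum(pr$valid), 15)
  # a cavity-filling notch shrinks r_in along its ray but stays valid
  img2 <- make_annulus(51, c(26, 26), r_in = 10, r_out = 20)
  img2[X > 1 & abs(Y) <= 1 & sqrt(X^2 + Y^2) <= 20] <- 1
  pr2 <- perimeter_radii(img2, n_theta = 24, center = c(26, 26))
  expect_true(pr2$valid[1])
  expect_lt(pr2$r_in[1], 4)
  expect_gt(pr2$r_in[7], 9)
})

test_that("custom crossing levels shift the recovered radii as specified", {
  # radial ramp: field falls linearly from 1 at the center to 0 at r = 20
  n <- 51
  X <- matrix(seq_len(n) - 26, n, n)
  Y <- matrix(seq_len(n) - 26, n, n, byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  img <- pmax(0, 1 - R / 20)
  pr <- perimeter_radii(img, n_theta = 8, center = c(26, 26),
                        level_in = 2, level_out = 0.25)
  # no up-crossing of level 2 exists -> invalid everywhere,
  # but the geometry of the 0.25 crossing is still testable via level_out
  expect_false(any(pr$valid))
  img_ann <- make_annulus(n, c(26, 26), 8, 16)
  pr2 <- perimeter_radii(0.8 * img_ann, n_theta = 8, level_in = 0.4,
                         level_out = 0.4)
  expect_true(all(pr2$valid))
  expect_true(all(abs(pr2$r_in - 8) < 0.5))
  expect_true(all(abs(pr2$r_out - 16) < 0.5))
})

test_that("angular averaging drops positions with too few valid rays", {
  prof <- data.frame(
    xi_mm = rep(c(1, 2), each = 4),
    theta = rep((0:3) * pi / 2, 2),
    psi_mm = c(1, 2, 3, 4, 10, 20, 30, 40),
    valid = c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
  av <- angular_average(prof, min_valid = 3)
  expect_identical(nrow(av), 1L)
  expect_equal(av$xi_mm, 1)
  expect_equal(av$psi_bar_mm, 2)      # mean of the valid 1, 2, 3
  expect_identical(av$n_valid, 3L)
  av2 <- angular_average(prof, min_valid = 1)
  expect_identical(nrow(av2), 2L)
  expect_equal(av2$psi_bar_mm[2], 10)
  # output ordered by xi even if input is shuffled
  av3 <- angular_average(prof[sample(8), ], min_valid = 1)
  expect_equal(av3$xi_mm, c(1, 2))
})

test_that("angular average of a cosine-modulated field is its mean", {
  th <- (0:24) * 2 * pi / 25
  prof <- data.frame(xi_mm = 1, theta = th, psi_mm = 5 + 0.5 * cos(th),
                     valid = TRUE)
  av <- angular_average(prof, min_valid = 13)
  expect_equal(av$psi_bar_mm, 5, tolerance = 1e-12)
})

test_that("CTG fit matches the closed-form least squares solution", {
  # exact line is recovered exactly
  xi <- seq(0.75, 1.95, by = 0.05)
  f <- fit_ctg(xi, 0.01 * xi + 0.1)
  expect_equal(f$k, 0.01, tolerance = 1e-12)
  expect_equal(f$m, 0.1, tolerance = 1e-12)
  expect_equal(f$rms, 0, tolerance = 1e-12)
  # constant profile: zero slope
  f0 <- fit_ctg(xi, rep(0.12, length(xi)))
  expect_equal(f0$k, 0, tolerance = 1e-12)
  # noisy data: agree with the independent closed-form formulas
  set.seed(5)
  y <- 0.008 * xi + 0.1 + rnorm(length(xi), sd = 0.003)
  f2 <- fit_ctg(xi, y)
  ref <- ols_line(xi, y)
  expect_equal(f2$k, unname(ref["k"]), tolerance = 1e-12)
  expect_equal(f2$m, unname(ref["m"]), tolerance = 1e-12)
  expect_error(fit_ctg(c(1, 1), c(1, 2)), "identical")
  expect_error(fit_ctg(1, 1), "at least 2")
})

test_that("CTI definitions give exact values on synthetic profiles", {
  prof <- data.frame(
    xi_mm = rep(1, 4), theta = (0:3) * pi / 2,
    r_in_mm = rep(0.1, 4), r_out_mm = rep(0.2, 4), valid = TRUE)
  prof$psi_mm <- prof$r_out_mm - prof$r_in_mm
  expect_equal(compute_cti(prof), 0.5, tolerance = 1e-12)
  expect_equal(compute_cti(prof, variant = "diameter"), 0.5,
               tolerance = 1e-12)
  # invalid rays are excluded
  prof$valid[1] <- FALSE
  prof$r_in_mm[1] <- 0
  expect_equal(compute_cti(prof), 0.5, tolerance = 1e-12)
  expect_error(compute_cti(transform(prof, valid = FALSE)), "valid")
})

test_that("CTI is scale invariant, CTG scales inversely with length units", {
  prof <- data.frame(
    xi_mm = rep(c(1, 2), each = 4), theta = rep((0:3) * pi / 2, 2),
    r_in_mm = c(rep(0.10, 4), rep(0.11, 4)),
    r_out_mm = rep(0.2, 8), valid = TRUE)
  prof$psi_mm <- prof$r_out_mm - prof$r_in_mm
  s <- transform(prof, r_in_mm = r_in_mm * 2, r_out_mm = r_out_mm * 2)
  expect_equal(compute_cti(s), compute_cti(prof), tolerance = 1e-12)
  # scaling xi and psi together leaves the dimensionless slope unchanged
  f1 <- fit_ctg(c(1, 2, 3), c(0.10, 0.11, 0.12))
  f2 <- fit_ctg(c(1, 2, 3) * 2, c(0.10, 0.11, 0.12) * 2)
  expect_equal(f1$k, f2$k, tolerance = 1e-12)
})

test_that("measure_bone on an analytic truth mask recovers the taper", {
  sp <- phantom_spec(n_slices = 80, r_in_mm = c(0.18, -0.010),
                     noise_sigma = 0, blur_sigma = 0, rng_seed = 31L)
  ph <- generate_phantom(sp)
  sd <- seed_annotation(40, 36 + 0.24 / 0.014599, 36, sp$joint_z)
  m <- measure_bone(ph$truth$mask, sd, voxel_size_um = sp$voxel_size_um,
                    range_mm = c(0.2, 1.0))
  expect_s3_class(m, "bone_metrics")
  expect_lt(abs(m$ctg - 0.010), 0.002)
  xr <- range(m$psi_bar$xi_mm)
  expect_lt(abs(m$cti / ph$truth$cti_true(xr) - 1), 0.02)
  expect_equal(unname(coef(m)["ctg"]), m$ctg)
  expect_equal(length(residuals(m)), m$n_slices)
  out <- capture.output(print(m))
  expect_true(any(grepl("CTG", out)))
})

test_that("grayscale measurement needs a stack; modes agree on clean data", {
  sp <- phantom_spec(n_slices = 60, noise_sigma = 0, blur_sigma = 0,
                     rng_seed = 33L)
  ph <- generate_phantom(sp)
  sd <- seed_annotation(30, 36 + 0.24 / 0.014599, 36, sp$joint_z)
  expect_error(measure_bone(ph$truth$mask, sd, range_mm = c(0.2, 0.7),
                            measure_on = "grayscale"),
               "stack")
  m_mask <- measure_bone(ph$truth$mask, sd, range_mm = c(0.2, 0.7),
                         measure_on = "mask")
  m_gray <- measure_bone(ph$truth$mask, sd, range_mm = c(0.2, 0.7),
                         stack = ph$stack)
  expect_lt(abs(m_gray$cti / m_mask$cti - 1), 0.02)
  expect_lt(abs(m_gray$ctg - m_mask$ctg), 0.002)
})
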