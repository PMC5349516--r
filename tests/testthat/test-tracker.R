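# Region labeling and slice-to-slice bone tracking.

test_that("label_regions finds 8-connected components with correct stats", {
  m <- matrix(FALSE, 6, 6)
  m[1:2, 1:2] <- TRUE          # block of 4
  m[5, 5] <- TRUE              # isolated pixel
  lab <- label_regions(m)
  expect_identical(nrow(lab$table), 2L)
  expect_setequal(lab$table$area, c(4L, 1L))
  blk <- lab$table[lab$table$area == 4L, ]
  expect_equal(c(blk$x, blk$y), c(1.5, 1.5))
  # diagonal touch is connected (8-connectivity)
  d <- matrix(FALSE, 4, 4)
  d[1, 1] <- TRUE; d[2, 2] <- TRUE
  expect_identical(nrow(label_regions(d)$table), 1L)
  # empty mask
  e <- label_regions(matrix(FALSE, 3, 3))
  expect_identical(nrow(e$table), 0L)
  expect_true(all(e$labels == 0L))
})

test_that("labels partition the foreground exactly", {
  set.seed(21)
  m <- matrix(runif(30 * 30) > 0.7, 30, 30)
  lab <- label_regions(m)
  expect_identical(lab$labels > 0L, m)
  expect_identical(sum(lab$table$area), sum(m))
})

test_that("successor choice prefers minimal area difference among overlaps", {
  # previous region: column band rows 4..9; two candidates overlap it:
  # a small one (area 2) and a big one (area 12); previous area 3
  m <- matrix(FALSE, 12, 12)
  m[4:5, 3] <- TRUE                 # candidate A, area 2
  m[7:9, 6:9] <- TRUE               # candidate B, area 12
  lab <- label_regions(m)
  prev_idx <- which(m)              # shadow covering both candidates
  la <- lab$labels[4, 3]; lb <- lab$labels[7, 6]
  got <- cortexCT:::pick_successor(lab, prev_idx, prev_area = 3,
                                   prev_centroid = c(6, 5))
  expect_identical(got, la)
  got2 <- cortexCT:::pick_successor(lab, prev_idx, prev_area = 11,
                                    prev_centroid = c(6, 5))
  expect_identical(got2, lb)
  # no overlap -> NULL
  expect_null(cortexCT:::pick_successor(lab, which(!m)[1], 3, c(1, 1)))
})

test_that("tracking a straight tube recovers the axis and areas", {
  vol <- make_tube_mask(c(40, 40, 30), c(20.5, 20.5), 6, 12)
  sd <- seed_annotation(seed_slice = 15, x = 20, y = 30, joint_z = 2)
  tr <- track_bone(vol, sd, voxel_size_um = 14.599,
                   range_mm = c(0.05, 0.35))
  expect_s3_class(tr, "bone_track")
  expect_equal(tr$centerline$x, rep(20.5, nrow(tr$centerline)),
               tolerance = 1e-9)
  expect_equal(tr$centerline$y, rep(20.5, nrow(tr$centerline)),
               tolerance = 1e-9)
  expect_true(all(diff(tr$centerline$slice) == 1L))
  expect_equal(length(unique(tr$areas)), 1L)
  # the isolated mask contains exactly the tube in the tracked range
  zr <- range(tr$centerline$slice)
  expect_identical(tr$mask[, , zr[1]:zr[2]], vol[, , zr[1]:zr[2]])
  expect_false(any(tr$mask[, , -(zr[1]:zr[2])]))
})

test_that("tracked slice range follows the mm interval above the joint", {
  vol <- make_tube_mask(c(30, 30, 60), c(15, 15), 4, 9)
  vox <- 14.599
  sd <- seed_annotation(seed_slice = 30, x = 15, y = 22, joint_z = 5)
  tr <- track_bone(vol, sd, voxel_size_um = vox, range_mm = c(0.2, 0.6))
  z_lo <- 5 + ceiling(0.2 / (vox / 1000))
  z_hi <- 5 + floor(0.6 / (vox / 1000))
  expect_identical(range(tr$centerline$slice), as.integer(c(z_lo, z_hi)))
})

test_that("tracking follows a drifting region and ignores a distractor", {
  d <- c(60, 30, 20)
  vol <- array(FALSE, d)
  X <- matrix(seq_len(d[1]), d[1], d[2])
  Y <- matrix(seq_len(d[2]), d[1], d[2], byrow = TRUE)
  for (z in seq_len(d[3])) {
    cx <- 15 + 0.8 * z                       # drifting target
    vol[, , z] <- (X - cx)^2 + (Y - 15)^2 <= 16
    vol[, , z][(X - 50)^2 + (Y - 15)^2 <= 4] <- TRUE   # static distractor
  }
  sd <- seed_annotation(seed_slice = 10, x = 23, y = 15, joint_z = 1)
  tr <- track_bone(vol, sd, voxel_size_um = 14.599, range_mm = c(0.02, 0.26))
  drift <- diff(tr$centerline$x)
  expect_true(all(drift > 0.4 & drift < 1.2))
  expect_true(all(abs(tr$centerline$y - 15) < 0.5))
  # distractor never captured
  expect_false(any(tr$mask[45:55, , ]))
})

test_that("tracking truncates with a warning when the region vanishes", {
  vol <- make_tube_mask(c(30, 30, 20), c(15, 15), 4, 9)
  vol[, , 15:20] <- FALSE
  sd <- seed_annotation(seed_slice = 10, x = 15, y = 22, joint_z = 1)
  expect_warning(
    tr <- track_bone(vol, sd, voxel_size_um = 14.599, range_mm = c(0.02, 0.26)),
    "truncated")
  expect_lte(max(tr$centerline$slice), 14L)
})

test_that("seed validation rejects bad annotations", {
  expect_error(seed_annotation(5, 1, 1, joint_z = 10), "joint_z")
  vol <- make_tube_mask(c(30, 30, 20), c(15, 15), 4, 9)
  sd_bg <- seed_annotation(10, x = 15, y = 15, joint_z = 1)  # in the cavity
  expect_error(track_bone(vol, sd_bg, 14.599, c(0.02, 0.26)), "foreground")
  sd_out <- seed_annotation(19, x = 15, y = 22, joint_z = 1)
  expect_error(track_bone(vol, sd_out, 14.599, c(0.02, 0.1)), "range")
})

test_that("tracking result is independent of the seed slice chosen", {
  vol <- make_tube_mask(c(30, 30, 25), c(15, 15), 4, 9)
  a <- track_bone(vol, seed_annotation(8, 15, 22, 1), 14.599, c(0.02, 0.3))
  b <- track_bone(vol, seed_annotation(18, 15, 22, 1), 14.599, c(0.02, 0.3))
  expect_identical(a$centerline, b$centerline)
  expect_identical(a$mask, b$mask)
})
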