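test_that("dice score obeys its closed-form oracles", {
  d <- c(8, 8, 8)
  a <- array(FALSE, d); a[2:5, 2:5, 2:5] <- TRUE
  expect_equal(dice_score(a, a), 1.0)
  b <- array(FALSE, d)
  expect_equal(dice_score(a, b), 0)
  expect_equal(dice_score(b, b), 0) # empty-empty defined as 0
  # |A| = |B| = n with half overlap: dice = 0.5 by direct count
  a2 <- array(FALSE, d); a2[1:4, 1, 1] <- TRUE
  b2 <- array(FALSE, d); b2[3:6, 1, 1] <- TRUE
  expect_equal(dice_score(a2, b2), 0.5)
  expect_equal(dice_score(a2, b2), dice_score(b2, a2))
})

test_that("thinning reduces a cylinder to its centerline", {
  d <- c(21L, 21L, 48L)
  vol <- array(0, d)
  for (k in 5:44) vol[, , k] <-
    outer(1:21, 1:21, function(i, j) (i - 11)^2 + (j - 11)^2 <= 16)
  sk <- skeletonize_ulm(vol, 0)
  # skeleton is a subset of the support
  expect_true(all(vol[sk == 1] == 1))
  # single connected centerline of about the cylinder's 40-voxel length
  expect_gte(sum(sk), 36)
  expect_lte(sum(sk), 44)
  idx <- which(sk == 1, arr.ind = TRUE)
  expect_true(all(abs(idx[, 1] - 11) <= 1), all(abs(idx[, 2] - 11) <= 1))
  # empty input: empty skeleton
  expect_equal(sum(skeletonize_ulm(array(0, c(6, 6, 6)))), 0)
})

test_that("vascular density is a per-volume centerline count", {
  v <- 0.1 # mm voxels: 1000 voxels per mm^3
  skel <- array(0L, c(20, 20, 20))
  skel[5, 5, 1:10] <- 1L
  roi <- array(TRUE, c(20, 20, 20))
  # 10 voxels in an 8 mm^3 ROI
  expect_equal(vascular_density(skel, roi, v), 10 / (8000 * 0.001))
  # linearity: doubling the centerline count doubles vd
  skel2 <- skel; skel2[6, 6, 1:10] <- 1L
  expect_equal(vascular_density(skel2, roi, v),
               2 * vascular_density(skel, roi, v))
  # ROI excluding the skeleton: zero; empty ROI rejected
  roi2 <- array(FALSE, c(20, 20, 20)); roi2[15:20, 15:20, 15:20] <- TRUE
  expect_equal(vascular_density(skel, roi2, v), 0)
  expect_error(vascular_density(skel, array(FALSE, c(20, 20, 20)), v),
               "ROI volume")
})

test_that("bilateral symmetry is exact on constructed volumes", {
  rv <- wavelength_mm() / 10
  ext <- c(40, 40, 40) * rv
  # mirror-symmetric tube pair
  tracks <- dplyr::bind_rows(
    manual_track(cbind(c(10, 30) * rv, rep(10.5 * rv, 2), c(8, 32) * rv),
                 track_id = 1L),
    manual_track(cbind(c(10, 30) * rv, rep(29.5 * rv, 2), c(8, 32) * rv),
                 track_id = 2L))
  img <- render_density(tracks, ext, rv)
  expect_equal(as.numeric(bilateral_symmetry(img, rotation_search = FALSE)),
               1.0)
  # everything in one hemisphere: no overlap with the reflection
  # (scored in place; lateral centering would fold it onto itself)
  left_only <- render_density(
    manual_track(cbind(c(10, 30) * rv, rep(6.5 * rv, 2), c(8, 32) * rv)),
    ext, rv)
  expect_equal(as.numeric(bilateral_symmetry(left_only,
                                             rotation_search = FALSE,
                                             center_lateral = FALSE)), 0)
  # empty image: flagged zero
  empty <- render_density(tracks[0, ], ext, rv)
  expect_warning(bs <- bilateral_symmetry(empty), "empty image")
  expect_equal(as.numeric(bs), 0)
})

test_that("rotational centering recovers a rotated symmetric image", {
  rv <- wavelength_mm() / 10
  ext <- c(48, 48, 48) * rv
  tracks <- dplyr::bind_rows(
    manual_track(cbind(c(8, 40) * rv, rep(14.5 * rv, 2), c(8, 40) * rv),
                 track_id = 1L),
    manual_track(cbind(c(8, 40) * rv, rep(33.5 * rv, 2), c(8, 40) * rv),
                 track_id = 2L),
    manual_track(cbind(rep(12.5 * rv, 2), c(10, 38) * rv, rep(24.5 * rv, 2)),
                 track_id = 3L))
  img <- render_density(tracks, ext, rv)
  base <- bilateral_symmetry(img)
  expect_gte(as.numeric(base), 0.98)
  # rotate the volume by 6 degrees about the depth axis and re-measure:
  # the grid search must recover most of the symmetry
  rot <- img
  rot$density <- vulm:::rotate_about_axis(img$density, 6, 1)
  rot$counts <- rot$density
  with_rot <- bilateral_symmetry(rot)
  without <- bilateral_symmetry(rot, rotation_search = FALSE)
  expect_gt(as.numeric(with_rot), as.numeric(without))
  expect_equal(attr(with_rot, "rotation_deg")[1], -6, tolerance = 1.01)
})

test_that("shell profiles read means over supported voxels only", {
  rv <- 0.05
  d <- c(60L, 80L, 60L)
  ext <- d * rv
  mid <- ext[2] / 2
  ctr_l <- c(1.5, 1.0, 1.5)
  spec <- shell_spec(ctr_l, midline_mm = mid,
                     radii = seq(0.25, 1.25, 0.25), thickness = 0.25)
  expect_equal(spec$center_right[2], 2 * mid - ctr_l[2])
  # uniform supported field at 10 mm/s: flat profile, zero difference
  vm <- structure(list(speed = array(10, d),
                       support_count = array(1L, d),
                       render_voxel_mm = rv, extent_mm = ext),
                  class = "velocity_map")
  prof <- shell_profiles(vm, spec)
  expect_equal(prof$mean_speed_left, rep(10, 5))
  expect_equal(prof$mean_speed_right, rep(10, 5))
  expect_equal(prof$difference, rep(0, 5))
  expect_true(all(prof$n_left > 0))

  # zero-flow core of radius 0.5 mm on the left: left means rise toward
  # the background with radius, right stays flat
  idx <- arrayInd(seq_len(prod(d)), d)
  dist_l <- sqrt(((idx[, 1] - 0.5) * rv - ctr_l[1])^2 +
                   ((idx[, 2] - 0.5) * rv - ctr_l[2])^2 +
                   ((idx[, 3] - 0.5) * rv - ctr_l[3])^2)
  vm2 <- vm
  vm2$speed <- array(ifelse(dist_l <= 0.5, 0, 12), d)
  vm2$support_count <- array(as.integer(dist_l > 0.5), d) # core unsupported
  prof2 <- shell_profiles(vm2, spec)
  expect_true(all(is.na(prof2$mean_speed_left[1:2]))) # empty core shells
  expect_equal(prof2$mean_speed_left[3:5], rep(12, 3))
  expect_equal(prof2$mean_speed_right, rep(12, 5))
  # supported-core variant: means increase monotonically through the edge
  vm3 <- vm2
  vm3$support_count <- array(1L, d)
  prof3 <- shell_profiles(vm3, spec)
  expect_equal(prof3$mean_speed_left[1], 0)
  expect_true(all(diff(prof3$mean_speed_left) >= 0))
  expect_equal(prof3$mean_speed_left[5], 12)
  # centers must be inside the grid
  bad <- shell_spec(c(-1, 0, 0), midline_mm = mid)
  expect_error(shell_profiles(vm, bad), "outside the grid")
})

test_that("default shell grid extends to 4 mm in quarter-mm steps", {
  sp <- shell_spec(c(1, 1, 1), midline_mm = 2)
  expect_equal(max(sp$radii), 4)
  expect_equal(unique(diff(sp$radii)), 0.25)
  expect_equal(sp$thickness, 0.25)
})
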