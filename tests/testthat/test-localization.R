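test_that("depth leveling flattens per-depth means exactly", {
  set.seed(2)
  arr <- array(abs(rnorm(8 * 6 * 5 * 7)) + 0.1, c(8, 6, 5, 7))
  lev <- level_depth_intensity(arr)
  expect_length(lev$v_dep, 8)
  # independent recomputation of the per-depth means after leveling
  post <- apply(lev$leveled, 1, mean)
  expect_equal(post, rep(1, 8), tolerance = 1e-9)
  # an intensity that is purely a function of depth levels to one
  ramp <- array(rep(1:8, 6 * 5 * 7), c(8, 6, 5, 7))
  expect_equal(level_depth_intensity(ramp)$leveled,
               array(1, dim(ramp)), tolerance = 1e-12)
  # zero-mean planes are exempted, not divided
  arr[3, , , ] <- 0
  expect_message(lev2 <- level_depth_intensity(arr), "exempted")
  expect_equal(sum(lev2$leveled[3, , , ]), 0)
})

test_that("volume enhancement follows the stated stage order and range", {
  cfg <- localization_config()
  # flat volume: opening equals the volume, top-hat is identically zero
  flat <- array(5, c(12, 12, 12))
  expect_equal(preprocess_volume(flat, cfg), array(0, dim(flat)))
  expect_equal(preprocess_volume(array(0, c(8, 8, 8)), cfg),
               array(0, c(8, 8, 8)))
  # blob on a linear ramp: the enhancement must suppress the ramp while
  # keeping the blob peak in place (explicit opening-subtraction oracle)
  d <- c(24, 24, 24)
  ramp <- array(rep(seq(0, 0.3, length.out = 24), each = 1), d) # depth ramp
  blob <- array(0, d)
  ctr <- c(12, 13, 11)
  for (i in -3:3) for (j in -3:3) for (k in -3:3) {
    blob[ctr[1] + i, ctr[2] + j, ctr[3] + k] <-
      exp(-sum(c(i, j, k)^2) / (2 * 0.85^2))
  }
  enh <- preprocess_volume(ramp + blob, cfg)
  expect_true(all(enh >= 0 & enh <= 1))
  expect_equal(as.integer(arrayInd(which.max(enh), d)), ctr)
  away <- enh[, , 1:5] # ramp-only region
  expect_lt(max(away), 0.5 * max(enh))
  # output is within [0,1] and bounded by input shape
  expect_equal(dim(enh), d)
})

test_that("weighted centroids are exact for symmetric blobs and split pairs", {
  cfg <- localization_config()
  v <- 0.0986
  d <- c(24, 24, 24)
  # a voxel-centered symmetric blob: centroid is that voxel center
  vol <- array(0, d)
  for (i in -3:3) for (j in -3:3) for (k in -3:3) {
    vol[12 + i, 14 + j, 10 + k] <- exp(-sum(c(i, j, k)^2) / (2 * 0.8^2))
  }
  loc <- segment_centroids(vol, 3L, cfg, v)
  expect_equal(nrow(loc), 1)
  expect_equal(loc$volume_index, 3L)
  expect_equal(loc$z_mm, (12 - 0.5) * v)
  expect_equal(loc$x_mm, (14 - 0.5) * v)
  expect_equal(loc$y_mm, (10 - 0.5) * v)

  # two separated blobs: two records, each within half a voxel of its
  # brute-force weighted mean
  vol2 <- array(0, d)
  ctrs <- rbind(c(6, 6, 6), c(18, 17, 16))
  for (b in 1:2) for (i in -3:3) for (j in -3:3) for (k in -3:3) {
    vol2[ctrs[b, 1] + i, ctrs[b, 2] + j, ctrs[b, 3] + k] <-
      vol2[ctrs[b, 1] + i, ctrs[b, 2] + j, ctrs[b, 3] + k] +
      exp(-sum(c(i, j, k)^2) / (2 * 0.9^2))
  }
  loc2 <- segment_centroids(vol2, 1L, cfg, v)
  loc2 <- loc2[order(loc2$z_mm), ]
  expect_equal(nrow(loc2), 2)
  thr <- mean(vol2) + cfg$final_threshold_k * sd(as.numeric(vol2))
  for (b in 1:2) {
    idx <- which(vol2 > thr, arr.ind = TRUE)
    mine <- idx[abs(idx[, 1] - ctrs[b, 1]) < 6, , drop = FALSE]
    w <- vol2[mine]
    ref <- colSums(mine * w) / sum(w) # brute-force weighted mean
    got <- c(loc2$z_mm[b], loc2$x_mm[b], loc2$y_mm[b]) / v + 0.5
    expect_lt(sqrt(sum((got - ref)^2)), 0.5)
  }

  # empty result allowed
  expect_equal(nrow(segment_centroids(array(0, c(6, 6, 6)), 1L, cfg, v)), 0)
})

test_that("localization order does not depend on processing order", {
  grid <- std_grid(24)
  starts <- lattice_starts(grid$extent_mm, n = 6, seed = 3)
  truth <- straight_truth(starts, c(0, 1, 0), 10, n_frames = 6)
  st <- synthesize_volume_stack(truth, grid, tissue_amplitude = 0,
                                noise_sigma = 0, seed = 1)
  all_at_once <- localize_stack(st, level = FALSE)
  reversed <- purrr::map_dfr(rev(seq_len(6)), function(f) {
    segment_centroids(preprocess_volume(st$data[, , , f]), f,
                      localization_config(), grid$voxel_size_mm)
  })
  reversed <- dplyr::arrange(reversed, volume_index, z_mm)
  all_at_once <- dplyr::arrange(all_at_once, volume_index, z_mm)
  expect_equal(as.data.frame(all_at_once), as.data.frame(reversed))
})
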