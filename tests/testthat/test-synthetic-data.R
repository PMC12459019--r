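test_that("acquisition constants derive correctly from the sequence", {
  acq <- acquisition_params()
  expect_equal(acq$wavelength_mm, 1540 / 7.81e6 * 1000)
  expect_equal(acq$voxel_size_mm, acq$wavelength_mm / 2)
  expect_equal(acq$volume_rate, 500)
  expect_equal(acq$n_volumes, 100000)
  # lambda/2 matches the printed 98.6 um to its precision
  expect_equal(round(acq$voxel_size_mm * 1000, 1), 98.6)
  expect_equal(psf_sigma_from_fwhm(2), 2 / (2 * sqrt(2 * log(2))))
  expect_equal(round(psf_sigma_from_fwhm(2), 1), 0.8)
  expect_equal(dataset_success_rate(33, 40), 82.5)
})

test_that("vessel network generation is deterministic, bounded and mirror-symmetric", {
  net1 <- generate_vessel_network(seed = 7)
  net2 <- generate_vessel_network(seed = 7)
  expect_identical(as.data.frame(net1), as.data.frame(net2))

  ext <- attr(net1, "domain_extent")
  for (cc in c("z0_mm", "z1_mm")) expect_true(all(net1[[cc]] >= 0 & net1[[cc]] <= ext[1]))
  for (cc in c("x0_mm", "x1_mm")) expect_true(all(net1[[cc]] >= 0 & net1[[cc]] <= ext[2]))
  for (cc in c("y0_mm", "y1_mm")) expect_true(all(net1[[cc]] >= 0 & net1[[cc]] <= ext[3]))
  expect_true(all(net1$radius_mm > 0))
  len <- sqrt((net1$z1_mm - net1$z0_mm)^2 + (net1$x1_mm - net1$x0_mm)^2 +
                (net1$y1_mm - net1$y0_mm)^2)
  expect_true(all(len > 0))
  # speeds drawn within the requested healthy range
  expect_true(all(net1$speed_mm_s >= 1 & net1$speed_mm_s <= 30))

  # the mirrored network rasterizes identically: centerline dice of 1
  for (seed in c(7, 21)) {
    net <- generate_vessel_network(seed = seed)
    a <- rasterize_network(net, 0.0986)
    b <- rasterize_network(mirror_network(net), 0.0986)
    expect_identical(a, b)
    expect_equal(dice_score(a, b), 1.0)
  }
  expect_error(generate_vessel_network(domain_extent = c(0.2, 0.2, 0.2)),
               "too small")
})

test_that("tumor model removes core segments and slows the periphery", {
  net <- generate_vessel_network(seed = 3)
  # degenerate lesion: nothing changes
  tum0 <- tumor_spec(center = c(3, 1.7, 3), core_radius = 0,
                     periphery_radius = 0)
  expect_identical(as.data.frame(apply_tumor_model(net, tum0, seed = 1)),
                   as.data.frame(net))
  # full dropout: no midpoint survives inside the core
  tum1 <- tumor_spec(center = c(3, 1.7, 3), core_radius = 1,
                     periphery_radius = 2, dropout_fraction = 1)
  les <- apply_tumor_model(net, tum1, seed = 1)
  midd <- sqrt(((les$z0_mm + les$z1_mm) / 2 - 3)^2 +
                 ((les$x0_mm + les$x1_mm) / 2 - 1.7)^2 +
                 ((les$y0_mm + les$y1_mm) / 2 - 3)^2)
  expect_equal(sum(midd <= 1), 0)
  # periphery speeds resampled into the slow tumor range
  tum2 <- tumor_spec(center = c(3, 1.7, 3), core_radius = 0.5,
                     periphery_radius = 2,
                     periphery_speed_range = c(0.1, 0.8),
                     dropout_fraction = 0.5)
  les2 <- apply_tumor_model(net, tum2, seed = 1)
  midd2 <- sqrt(((les2$z0_mm + les2$z1_mm) / 2 - 3)^2 +
                  ((les2$x0_mm + les2$x1_mm) / 2 - 1.7)^2 +
                  ((les2$y0_mm + les2$y1_mm) / 2 - 3)^2)
  in_periph <- midd2 <= 2
  expect_true(any(in_periph))
  expect_true(all(les2$speed_mm_s[in_periph] >= 0.1 &
                    les2$speed_mm_s[in_periph] <= 0.8))
  # segments outside the periphery untouched
  outside_ids <- les2$segment_id[!in_periph]
  orig <- net[match(outside_ids, net$segment_id), ]
  expect_equal(les2$speed_mm_s[!in_periph], orig$speed_mm_s)
  # tumor center must be inside the domain
  expect_error(apply_tumor_model(net, tumor_spec(center = c(99, 0, 0))),
               "inside the domain")
})

test_that("microbubble transits advect at the segment speed", {
  ext <- c(6.3, 6.3, 6.3)
  seg <- vulm:::single_segment_network(ext, speed = 10)
  tr <- simulate_mb_transits(seg, n_volumes = 50, volume_rate = 500,
                             mean_mb_per_volume = 3, seed = 1)
  expect_true(all(tr$volume_index >= 1 & tr$volume_index <= 50))
  # along-centerline displacement is exactly speed / volume_rate
  one <- tr[tr$bubble_id == tr$bubble_id[1], ]
  one <- one[order(one$volume_index), ]
  expect_true(nrow(one) > 2)
  expect_equal(diff(one$x_mm), rep(10 / 500, nrow(one) - 1))
  # radial jitter stays within the vessel radius
  d_center <- sqrt((tr$z_mm - seg$z0_mm)^2 + (tr$y_mm - seg$y0_mm)^2)
  expect_true(all(d_center <= seg$radius_mm + 1e-12))

  # zero speed: positions constant across frames
  seg0 <- vulm:::single_segment_network(ext, speed = 0)
  tr0 <- simulate_mb_transits(seg0, n_volumes = 20, mean_mb_per_volume = 2,
                              seed = 2)
  per <- dplyr::summarise(dplyr::group_by(tr0, bubble_id),
                          moved = max(z_mm) - min(z_mm) +
                            max(x_mm) - min(x_mm) + max(y_mm) - min(y_mm))
  expect_true(all(per$moved == 0))

  # determinism and empty-network rejection
  tr2 <- simulate_mb_transits(seg, n_volumes = 50, mean_mb_per_volume = 3,
                              seed = 1)
  expect_identical(as.data.frame(tr), as.data.frame(tr2))
  empty <- seg[0, ]
  expect_error(simulate_mb_transits(empty, n_volumes = 10), "no segments")
})

test_that("realized bubble load matches the study's per-volume density", {
  net <- generate_vessel_network(seed = 5)
  tr <- simulate_mb_transits(net, n_volumes = 200, mean_mb_per_volume = 80,
                             seed = 6)
  counts <- tabulate(tr$volume_index, 200)
  expect_gte(mean(counts), 60)
  expect_lte(mean(counts), 100)
})

test_that("synthesized stacks place blobs at the true positions", {
  grid <- std_grid(32)
  v <- grid$voxel_size_mm
  # one static bubble at a known subvoxel position, clean background
  truth <- straight_truth(matrix(c(16.3, 15.7, 16.05) * v, 1), c(1, 0, 0),
                          speed = 0, n_frames = 5)
  st <- synthesize_volume_stack(truth, grid, tissue_amplitude = 0,
                                noise_sigma = 0, seed = 1)
  expect_s3_class(st, "volume_stack")
  expect_true(all(st$data >= 0))
  for (f in 1:5) {
    am <- arrayInd(which.max(st$data[, , , f]), grid$dim)
    expect_equal(as.integer(am),
                 as.integer(floor(c(16.3, 15.7, 16.05))) + 1L)
  }
  # blob FWHM spans two half-wavelength voxels for a one-wavelength PSF
  prof <- st$data[, 16, 17, 1]
  peak <- max(prof)
  expect_equal(sum(prof >= peak / 2), 2)

  # no bubbles: every frame equals the static tissue field
  empty <- truth[0, ]
  attr(empty, "n_volumes") <- 4L
  st2 <- synthesize_volume_stack(empty, grid, tissue_amplitude = 10,
                                 noise_sigma = 0, seed = 2)
  for (f in 2:4) expect_equal(st2$data[, , , f], st2$data[, , , 1])

  # bubbles outside the grid are clipped with a message, not an error
  out_truth <- straight_truth(matrix(c(-5, -5, -5), 1), c(1, 0, 0), 0, 2)
  expect_message(
    st3 <- synthesize_volume_stack(out_truth, grid, tissue_amplitude = 0,
                                   noise_sigma = 0, seed = 1),
    "clipped")
  expect_equal(attr(st3, "n_clipped"), 2L)
  expect_equal(max(st3$data), 0)
})

test_that("streamed synthesis reproduces the bubble content batchwise", {
  grid <- std_grid(16)
  starts <- lattice_starts(grid$extent_mm, n = 5)
  truth <- straight_truth(starts, c(0, 1, 0), speed = 10, n_frames = 8)
  full <- synthesize_volume_stack(truth, grid, tissue_amplitude = 0,
                                  noise_sigma = 0, seed = 1)
  part <- synthesize_volume_stack(truth, grid, tissue_amplitude = 0,
                                  noise_sigma = 0, seed = 1, frames = 5:8)
  expect_equal(part$data, full$data[, , , 5:8, drop = FALSE])
})
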