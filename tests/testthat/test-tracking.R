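test_that("frame-to-frame assignment minimizes total distance (brute-force oracle)", {
  # two bubbles crossing paths over 5 frames plus a third wanderer:
  # the Hungarian linking must equal exhaustive minimum-cost matching
  withr::with_seed(42, {
    for (rep in 1:5) {
      n <- sample(2:3, 1)
      pos <- matrix(runif(n * 3, 0, 0.5), n, 3)
      vel <- matrix(runif(n * 3, -0.02, 0.02), n, 3)
      locs <- purrr::map_dfr(1:5, function(f) {
        p <- pos + vel * (f - 1)
        tibble::tibble(volume_index = f, z_mm = p[, 1], x_mm = p[, 2],
                       y_mm = p[, 3])
      })
      tracks <- link_tracks(locs, tracking_config(max_link_distance = 10))
      # every frame transition must match the brute-force assignment
      for (f in 1:4) {
        a <- as.matrix(locs[locs$volume_index == f, c("z_mm", "x_mm", "y_mm")])
        b <- as.matrix(locs[locs$volume_index == f + 1,
                            c("z_mm", "x_mm", "y_mm")])
        cost <- outer(seq_len(nrow(a)), seq_len(nrow(b)),
                      Vectorize(function(i, j) sqrt(sum((a[i, ] - b[j, ])^2))))
        ref <- brute_force_assignment(cost)$assignment
        key <- function(df) paste(round(df$z_mm, 9), round(df$x_mm, 9),
                                  round(df$y_mm, 9))
        tf <- tracks[tracks$volume_index == f, ]
        tg <- tracks[tracks$volume_index == f + 1, ]
        ta <- tf$track_id[match(key(locs[locs$volume_index == f, ]),
                                key(tf))]
        tb <- tg$track_id[match(key(locs[locs$volume_index == f + 1, ]),
                                key(tg))]
        expect_equal(ta, tb[ref])
      }
    }
  })
})

test_that("link gating splits tracks and single detections chain up", {
  # one detection per frame, small displacement: a single track
  locs <- tibble::tibble(volume_index = 1:20, z_mm = 1,
                         x_mm = 1 + 0.01 * (0:19), y_mm = 2)
  tr <- link_tracks(locs, tracking_config(max_link_distance = 0.2))
  expect_equal(dplyr::n_distinct(tr$track_id), 1)
  expect_equal(nrow(tr), 20)
  # one jump beyond the gate: the track splits in two
  locs2 <- locs
  locs2$x_mm[11:20] <- locs2$x_mm[11:20] + 5
  tr2 <- link_tracks(locs2, tracking_config(max_link_distance = 0.2))
  expect_equal(dplyr::n_distinct(tr2$track_id), 2)
  expect_equal(as.integer(table(tr2$track_id)), c(10L, 10L))
  # partition property: every localization lands in exactly one track
  expect_equal(sort(tr2$volume_index), sort(locs2$volume_index))
})

test_that("short tracks are discarded and the smoother is exact on cubics", {
  cfg <- tracking_config()
  f <- 1:30
  cubic <- 0.1 + 0.02 * f - 1e-3 * f^2 + 2e-5 * f^3
  tracks <- dplyr::bind_rows(
    tibble::tibble(track_id = 1L, volume_index = f, z_mm = cubic,
                   x_mm = rev(cubic), y_mm = 0.5 + 0 * f),
    tibble::tibble(track_id = 2L, volume_index = 1:9, z_mm = 1,
                   x_mm = 1, y_mm = 1) # nine points: dropped
  )
  sm <- smooth_and_filter(tracks, cfg)
  expect_equal(unique(sm$track_id), 1L)
  # a third-order filter reproduces polynomials of degree <= 3 exactly
  expect_equal(sm$zs_mm, cubic, tolerance = 1e-10)
  expect_equal(sm$xs_mm, rev(cubic), tolerance = 1e-10)
  expect_equal(sm$ys_mm, rep(0.5, 30), tolerance = 1e-12)
})

test_that("smoothing reduces deviation from a noisy straight path", {
  withr::with_seed(9, {
    f <- 1:50
    true_x <- 0.5 + 0.004 * f
    noisy <- true_x + rnorm(50, sd = 0.004)
    tracks <- tibble::tibble(track_id = 1L, volume_index = f,
                             z_mm = 1, x_mm = noisy, y_mm = 1)
    sm <- smooth_and_filter(tracks, tracking_config())
    rms_raw <- sqrt(mean((noisy - true_x)^2))
    rms_sm <- sqrt(mean((sm$xs_mm - true_x)^2))
    expect_lt(rms_sm, rms_raw)
  })
})

test_that("segment speeds are distance times volume rate", {
  pts <- cbind(c(0, 0.0986, 0.0986), c(1, 1, 1), c(2, 2, 2))
  tr <- manual_track(pts)
  out <- compute_velocities(tr, volume_rate = 500)
  expect_equal(out$segment_speed_mm_s, c(0.0986 * 500, 0, NA_real_))
  expect_equal(out$segment_speed_mm_s[1], 49.3)
})

test_that("a constant-speed bubble's velocity is recovered end to end", {
  grid <- std_grid(32)
  ext <- grid$extent_mm
  truth <- straight_truth(matrix(ext * c(0.5, 0.1, 0.5), 1), c(0, 1, 0),
                          speed = 10, n_frames = 60)
  st <- synthesize_volume_stack(truth, grid, tissue_amplitude = 0,
                                noise_sigma = 0, seed = 1)
  tk <- track_microbubbles(localize_stack(st, level = FALSE),
                           tracking_config(), volume_rate = 500)
  expect_equal(dplyr::n_distinct(tk$track_id), 1)
  mean_speed <- mean(tk$segment_speed_mm_s, na.rm = TRUE)
  expect_lt(abs(mean_speed - 10) / 10, 0.1)
})
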