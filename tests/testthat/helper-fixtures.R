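# shared helpers for building small deterministic fixtures in code

std_grid <- function(n = 32) grid_spec(c(n, n, n), wavelength_mm() / 2)

# ground-truth table for bubbles on straight constant-speed paths
straight_truth <- function(start, direction, speed, n_frames,
                           volume_rate = 500) {
  direction <- direction / sqrt(sum(direction^2))
  step <- speed / volume_rate
  rows <- purrr::map_dfr(seq_len(nrow(start)), function(b) {
    tibble::tibble(
      bubble_id = b, segment_id = 1L, volume_index = seq_len(n_frames),
      z_mm = start[b, 1] + direction[1] * step * (seq_len(n_frames) - 1),
      x_mm = start[b, 2] + direction[2] * step * (seq_len(n_frames) - 1),
      y_mm = start[b, 3] + direction[3] * step * (seq_len(n_frames) - 1),
      true_speed_mm_s = speed)
  })
  structure(rows, n_volumes = as.integer(n_frames),
            volume_rate = volume_rate)
}

# well-separated jittered-lattice bubble positions inside extent
lattice_starts <- function(extent, n = 20, margin = 0.12, seed = 1) {
  g <- as.matrix(expand.grid(z = seq(margin, 1 - margin, length.out = 3),
                             x = seq(margin, 1 - margin, length.out = 3),
                             y = seq(margin, 1 - margin, length.out = 3)))
  g <- g[seq_len(n), , drop = FALSE] * rep(extent, each = n)
  withr::with_seed(seed, g + matrix(runif(3 * n, -0.08, 0.08), n, 3))
}

# distance from every truth record to the nearest detection in its frame
nearest_detection_error <- function(truth, locs) {
  vapply(seq_len(nrow(truth)), function(i) {
    l <- locs[locs$volume_index == truth$volume_index[i], ]
    if (nrow(l) == 0) return(NA_real_)
    min(sqrt((l$z_mm - truth$z_mm[i])^2 + (l$x_mm - truth$x_mm[i])^2 +
               (l$y_mm - truth$y_mm[i])^2))
  }, numeric(1))
}

# minimal smoothed-track tibble for render tests
manual_track <- function(points, track_id = 1L, speed = NULL) {
  n <- nrow(points)
  tibble::tibble(
    track_id = track_id, volume_index = seq_len(n),
    z_mm = points[, 1], x_mm = points[, 2], y_mm = points[, 3],
    zs_mm = points[, 1], xs_mm = points[, 2], ys_mm = points[, 3],
    segment_speed_mm_s = if (is.null(speed)) NA_real_ else
      c(rep(speed, n - 1), NA_real_))
}

# brute-force minimum-cost assignment over all column permutations
brute_force_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }), recursive = FALSE)
  }
  best <- Inf; best_p <- NULL
  for (cols in utils::combn(seq_len(m), n, simplify = FALSE)) {
    for (p in perms(cols)) {
      tot <- sum(cost[cbind(seq_len(n), p)])
      if (tot < best - 1e-12) { best <- tot; best_p <- p }
    }
  }
  list(cost = best, assignment = best_p)
}
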