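#' Simulate microbubble transits through a vessel network
#'
#' Bubbles enter each segment as a seeded Poisson process, advect along
#' the centerline at the segment speed (one step of
#' `speed / volume_rate` mm per volume), and vanish at the segment end.
#' Entry rates are allocated proportionally to segment length so the
#' expected number of bubbles present per volume equals
#' `mean_mb_per_volume`; entries before frame one are included so the
#' count is stationary from the first volume. Each bubble keeps a fixed
#' radial offset, drawn uniformly within the vessel radius in the plane
#' perpendicular to the centerline, giving vessels finite width in the
#' rendered image while leaving the along-centerline displacement exactly
#' `speed / volume_rate` per frame.
#'
#' @param network A `vessel_network` with at least one segment.
#' @param n_volumes Number of volumes (time frames) to simulate.
#' @param volume_rate Volumetric frame rate, Hz.
#' @param mean_mb_per_volume Target mean number of bubbles per volume.
#' @param radial_jitter If `FALSE`, bubbles travel exactly on the
#'   centerline (used by localization-accuracy tests).
#' @param seed Integer RNG seed.
#' @return A tibble of ground-truth records: `bubble_id`, `segment_id`,
#'   `volume_index` (1-based, in `[1, n_volumes]`), position `z_mm`,
#'   `x_mm`, `y_mm`, and `true_speed_mm_s`; `n_volumes` and `volume_rate`
#'   are carried as attributes.
#' @examples
#' net <- generate_vessel_network(seed = 1)
#' truth <- simulate_mb_transits(net, n_volumes = 50, seed = 2)
#' nrow(truth) / 50 # about mean_mb_per_volume
#' @export
simulate_mb_transits <- function(network, n_volumes, volume_rate = 500,
                                 mean_mb_per_volume = 80,
                                 radial_jitter = TRUE, seed = 1) {
  if (nrow(network) == 0) {
    stop("simulate_mb_transits: network has no segments")
  }
  stopifnot(n_volumes >= 1, volume_rate > 0, mean_mb_per_volume > 0)
  p0 <- cbind(network$z0_mm, network$x0_mm, network$y0_mm)
  p1 <- cbind(network$z1_mm, network$x1_mm, network$y1_mm)
  lens <- sqrt(rowSums((p1 - p0)^2))
  dirs <- (p1 - p0) / lens
  step <- network$speed_mm_s / volume_rate        # mm per frame
  dwell <- ifelse(step > 0, lens / step, Inf)     # frames in transit
  dwell <- pmin(dwell, n_volumes)
  w <- lens / sum(lens)
  n_target <- mean_mb_per_volume * w              # concurrent bubbles
  rate <- n_target / dwell                        # entries per frame

  recs <- with_seed(seed, {
    out <- vector("list", nrow(network))
    next_id <- 1L
    for (s in seq_len(nrow(network))) {
      n_entries <- rpois(1, rate[s] * (n_volumes + dwell[s]))
      if (n_entries == 0) next
      t0 <- runif(n_entries, -dwell[s], n_volumes)
      # radial offset in the plane perpendicular to the centerline
      e1 <- perp_basis(dirs[s, ])
      u <- sqrt(runif(n_entries)) * network$radius_mm[s]
      th <- runif(n_entries, 0, 2 * pi)
      off <- outer(u * cos(th), e1$a) + outer(u * sin(th), e1$b)
      if (!radial_jitter) off[] <- 0
      frames <- lapply(seq_len(n_entries), function(b) {
        f <- seq.int(max(1L, ceiling(t0[b])), n_volumes)
        arc <- (f - t0[b]) * step[s]
        if (step[s] == 0) {
          keep <- f - t0[b] <= dwell[s]
          arc <- arc[keep]
        } else {
          keep <- arc <= lens[s]
          arc <- arc[keep]
        }
        f <- f[keep]
        if (length(f) == 0) return(NULL)
        pos <- matrix(p0[s, ], length(f), 3, byrow = TRUE) +
          outer(arc, dirs[s, ]) +
          matrix(off[b, ], length(f), 3, byrow = TRUE)
        tibble::tibble(bubble_id = NA_integer_, frame = f,
                       z_mm = pos[, 1], x_mm = pos[, 2], y_mm = pos[, 3])
      })
      frames <- dplyr::bind_rows(frames[!vapply(frames, is.null, TRUE)],
                                 .id = "entry")
      if (nrow(frames) == 0) next
      frames$bubble_id <- next_id + as.integer(frames$entry) - 1L
      next_id <- next_id + n_entries
      frames$entry <- NULL
      frames$segment_id <- network$segment_id[s]
      frames$true_speed_mm_s <- network$speed_mm_s[s]
      out[[s]] <- frames
    }
    dplyr::bind_rows(out)
  })
  if (nrow(recs) == 0) {
    recs <- tibble::tibble(bubble_id = integer(), segment_id = integer(),
                           frame = integer(), z_mm = numeric(),
                           x_mm = numeric(), y_mm = numeric(),
                           true_speed_mm_s = numeric())
  }
  recs <- dplyr::select(recs, "bubble_id", "segment_id",
                        volume_index = "frame",
                        "z_mm", "x_mm", "y_mm", "true_speed_mm_s")
  recs <- dplyr::arrange(recs, .data$volume_index, .data$bubble_id)
  structure(recs, n_volumes = as.integer(n_volumes),
            volume_rate = volume_rate)
}

# two unit vectors spanning the plane perpendicular to v
perp_basis <- function(v) {
  ref <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a <- ref - sum(ref * v) * v
  a <- a / sqrt(sum(a^2))
  b <- c(v[2] * a[3] - v[3] * a[2],
         v[3] * a[1] - v[1] * a[3],
         v[1] * a[2] - v[2] * a[1])
  list(a = a, b = b)
}
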