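#' Tracking configuration
#'
#' @param max_link_distance Maximum frame-to-frame link distance, mm.
#'   The default 0.2 mm gates physiologically impossible jumps
#'   (100 mm/s at 500 vps) while tolerating fast arterial flow.
#' @param sg_order Savitzky-Golay polynomial order (3).
#' @param sg_window Savitzky-Golay window length in points (9, odd).
#' @param min_track_points Minimum points for a track to survive (10).
#' @return A list of class `tracking_config`.
#' @export
tracking_config <- function(max_link_distance = 0.2,
                            sg_order = 3,
                            sg_window = 9,
                            min_track_points = 10) {
  stopifnot(max_link_distance > 0,
            sg_window %% 2 == 1, sg_window > sg_order,
            min_track_points >= sg_window)
  structure(list(max_link_distance = max_link_distance,
                 sg_order = sg_order, sg_window = sg_window,
                 min_track_points = min_track_points),
            class = "tracking_config")
}

#' Link localizations into tracks
#'
#' Frame-to-frame assignment by the Hungarian algorithm: between each pair
#' of consecutive volumes the total Euclidean distance of the matching is
#' minimized, links longer than `max_link_distance` are forbidden,
#' unmatched detections start new tracks, and a terminated track never
#' resumes (no gap closing). Cost ties are resolved deterministically by
#' the lowest detection index.
#'
#' @param localizations Tibble from [localize_stack()], sorted by
#'   `volume_index`.
#' @param config A [tracking_config()].
#' @return Tibble of raw track points: `track_id`, `volume_index`,
#'   `z_mm`, `x_mm`, `y_mm`.
#' @export
link_tracks <- function(localizations, config = tracking_config()) {
  loc <- dplyr::arrange(localizations, .data$volume_index)
  if (nrow(loc) == 0) {
    return(tibble::tibble(track_id = integer(), volume_index = integer(),
                          z_mm = numeric(), x_mm = numeric(),
                          y_mm = numeric()))
  }
  gate <- config$max_link_distance
  big <- 1e6 # forbidden-link cost, far above any feasible total
  frames <- split(seq_len(nrow(loc)), loc$volume_index)
  frame_ids <- as.integer(names(frames))
  pos <- as.matrix(loc[, c("z_mm", "x_mm", "y_mm")])

  track_of <- integer(nrow(loc)) # track id per localization row
  next_track <- 0L
  active_rows <- integer(0)      # rows of the previous frame still active
  prev_frame <- NA_integer_

  for (fi in seq_along(frames)) {
    rows <- frames[[fi]]
    f <- frame_ids[fi]
    if (length(active_rows) == 0 || is.na(prev_frame) || f != prev_frame + 1L) {
      # gap in frames: all active tracks terminate, detections start fresh
      track_of[rows] <- next_track + seq_along(rows)
      next_track <- next_track + length(rows)
      active_rows <- rows
      prev_frame <- f
      next
    }
    na <- length(active_rows); nd <- length(rows)
    D <- sqrt(outer(pos[active_rows, 1], pos[rows, 1], "-")^2 +
              outer(pos[active_rows, 2], pos[rows, 2], "-")^2 +
              outer(pos[active_rows, 3], pos[rows, 3], "-")^2)
    C <- matrix(big, max(na, nd), max(na, nd))
    C[seq_len(na), seq_len(nd)] <- ifelse(D <= gate, D, big)
    assign <- lsap_solve(C)
    new_active <- integer(0)
    matched <- rep(FALSE, nd)
    for (a in seq_len(na)) {
      j <- assign[a]
      if (j <= nd && D[a, j] <= gate) {
        track_of[rows[j]] <- track_of[active_rows[a]]
        matched[j] <- TRUE
        new_active <- c(new_active, rows[j])
      }
    }
    if (any(!matched)) {
      fresh <- rows[!matched]
      track_of[fresh] <- next_track + seq_along(fresh)
      next_track <- next_track + length(fresh)
      new_active <- c(new_active, fresh)
    }
    active_rows <- new_active
    prev_frame <- f
  }
  out <- tibble::tibble(track_id = track_of,
                        volume_index = loc$volume_index,
                        z_mm = loc$z_mm, x_mm = loc$x_mm, y_mm = loc$y_mm)
  out$track_id <- match(out$track_id, unique(out$track_id[order(out$volume_index)]))
  dplyr::arrange(out, .data$track_id, .data$volume_index)
}

#' Discard short tracks and smooth the survivors
#'
#' Tracks with fewer than `min_track_points` points are discarded; each
#' coordinate of the survivors is smoothed independently with a
#' third-order Savitzky-Golay filter over a nine-point window (endpoints
#' handled by the filter's polynomial extension), so trajectories that
#' follow a cubic polynomial pass through unchanged.
#'
#' @param tracks Raw tracks from [link_tracks()].
#' @param config A [tracking_config()].
#' @return Tibble with added smoothed coordinates `zs_mm`, `xs_mm`,
#'   `ys_mm`.
#' @export
smooth_and_filter <- function(tracks, config = tracking_config()) {
  keep <- dplyr::add_count(tracks, .data$track_id, name = ".n")
  keep <- dplyr::filter(keep, .data$.n >= config$min_track_points)
  keep$.n <- NULL
  if (nrow(keep) == 0) {
    keep$zs_mm <- numeric(0); keep$xs_mm <- numeric(0)
    keep$ys_mm <- numeric(0)
    return(keep)
  }
  sg <- function(x) {
    as.numeric(signal::sgolayfilt(x, p = config$sg_order,
                                  n = config$sg_window))
  }
  keep <- dplyr::group_by(keep, .data$track_id)
  keep <- dplyr::mutate(keep,
                        zs_mm = sg(.data$z_mm),
                        xs_mm = sg(.data$x_mm),
                        ys_mm = sg(.data$y_mm))
  dplyr::ungroup(keep)
}

#' Per-segment speeds from smoothed tracks
#'
#' The speed of each track segment is the Euclidean distance between
#' consecutive smoothed points multiplied by the volume rate, in mm/s.
#' The speed of segment `i -> i+1` is stored on row `i`; the last row of
#' each track carries `NA`.
#'
#' @param tracks Smoothed tracks from [smooth_and_filter()].
#' @param volume_rate Volumetric frame rate, Hz.
#' @return Input tibble with an added `segment_speed_mm_s` column.
#' @export
compute_velocities <- function(tracks, volume_rate = 500) {
  stopifnot(volume_rate > 0)
  if (nrow(tracks) == 0) {
    tracks$segment_speed_mm_s <- numeric(0)
    return(tracks)
  }
  tracks <- dplyr::group_by(tracks, .data$track_id)
  tracks <- dplyr::mutate(
    tracks,
    segment_speed_mm_s = sqrt(
      (dplyr::lead(.data$zs_mm) - .data$zs_mm)^2 +
      (dplyr::lead(.data$xs_mm) - .data$xs_mm)^2 +
      (dplyr::lead(.data$ys_mm) - .data$ys_mm)^2) * volume_rate)
  dplyr::ungroup(tracks)
}

#' Full tracking chain
#'
#' [link_tracks()], then [smooth_and_filter()], then
#' [compute_velocities()].
#'
#' @inheritParams link_tracks
#' @inheritParams compute_velocities
#' @return Smoothed tracks with per-segment speeds.
#' @export
track_microbubbles <- function(localizations, config = tracking_config(),
                               volume_rate = 500) {
  localizations |>
    link_tracks(config) |>
    smooth_and_filter(config) |>
    compute_velocities(volume_rate)
}
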