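#' Spherical-shell specification for hemodynamic profiling
#'
#' Concentric spherical shells grown from a tumoral-side point and its
#' contralateral mirror (same depth and elevation, lateral coordinate
#' reflected about the midline). Default radii extend to 4 mm in 0.25 mm
#' steps with 0.25 mm shell thickness.
#'
#' @param center_left 3-vector, mm: (depth, lateral, elevation) of the
#'   tumoral-side point.
#' @param midline_mm Lateral coordinate of the sagittal midline, mm; used
#'   to mirror `center_left` when `center_right` is not given.
#' @param center_right Optional explicit contralateral point.
#' @param radii Ascending outer radii, mm.
#' @param thickness Shell thickness, mm.
#' @return A list of class `shell_spec`.
#' @export
shell_spec <- function(center_left, midline_mm = NULL, center_right = NULL,
                       radii = seq(0.25, 4, by = 0.25), thickness = 0.25) {
  stopifnot(length(center_left) == 3, all(diff(radii) > 0), thickness > 0)
  if (is.null(center_right)) {
    if (is.null(midline_mm)) {
      stop("shell_spec: give either center_right or midline_mm")
    }
    center_right <- center_left
    center_right[2] <- 2 * midline_mm - center_left[2]
  }
  stopifnot(length(center_right) == 3)
  structure(list(center_left = center_left, center_right = center_right,
                 radii = radii, thickness = thickness),
            class = "shell_spec")
}

#' Mean bubble speed in concentric spherical shells
#'
#' For each outer radius `r` the shell holds the voxels at distance
#' `(r - thickness, r]` from the center. Means are taken over supported
#' voxels only (voxels some track actually traversed) — unsupported
#' voxels carry no speed sample; a shell with no supported voxel yields
#' `NA`, not 0. The hemisphere difference is left minus right
#' (tumoral minus contralateral), so slowed tumoral flow appears as
#' negative values.
#'
#' @param vmap A median-filtered [render_velocity()] map (see
#'   [median_filter_velocity()]).
#' @param spec A [shell_spec()].
#' @return A tibble with one row per radius: `radius_mm`,
#'   `mean_speed_left`, `mean_speed_right`, `difference`
#'   (left - right), `n_left`, `n_right` (supported voxels per shell).
#' @export
shell_profiles <- function(vmap, spec) {
  stopifnot(inherits(vmap, "velocity_map"), inherits(spec, "shell_spec"))
  d <- dim(vmap$speed)
  v <- vmap$render_voxel_mm
  for (ctr in list(spec$center_left, spec$center_right)) {
    if (any(ctr < 0) || any(ctr > d * v)) {
      stop("shell_profiles: shell center outside the grid")
    }
  }
  sup <- which(vmap$support_count > 0)
  if (length(sup) == 0) {
    return(tibble::tibble(radius_mm = spec$radii,
                          mean_speed_left = NA_real_,
                          mean_speed_right = NA_real_,
                          difference = NA_real_,
                          n_left = 0L, n_right = 0L))
  }
  idx <- arrayInd(sup, d)
  pos <- (idx - 0.5) * v
  speeds <- vmap$speed[sup]
  one_side <- function(center) {
    dist <- sqrt((pos[, 1] - center[1])^2 + (pos[, 2] - center[2])^2 +
                 (pos[, 3] - center[3])^2)
    purrr::map_dfr(spec$radii, function(r) {
      in_shell <- dist > r - spec$thickness & dist <= r
      tibble::tibble(
        radius_mm = r,
        mean_speed = if (any(in_shell)) mean(speeds[in_shell]) else NA_real_,
        n_voxels = sum(in_shell))
    })
  }
  left <- one_side(spec$center_left)
  right <- one_side(spec$center_right)
  tibble::tibble(
    radius_mm = spec$radii,
    mean_speed_left = left$mean_speed,
    mean_speed_right = right$mean_speed,
    difference = left$mean_speed - right$mean_speed,
    n_left = left$n_voxels,
    n_right = right$n_voxels
  )
}
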