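#' Isotropic voxel grid specification
#'
#' Describes a 3-D isotropic voxel grid with its origin at 0 mm on every
#' axis. Axes are ordered (depth, lateral, elevation); the center of voxel
#' `i` along an axis sits at `(i - 0.5) * voxel_size_mm`.
#'
#' @param dim Integer 3-vector of voxel counts (depth, lateral, elevation).
#' @param voxel_size_mm Isotropic voxel edge, mm.
#' @return An object of class `grid_spec`.
#' @examples
#' grid_spec(c(64, 64, 64), 0.0986)
#' @export
grid_spec <- function(dim, voxel_size_mm) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1), voxel_size_mm > 0)
  structure(
    list(dim = dim, voxel_size_mm = voxel_size_mm,
         extent_mm = dim * voxel_size_mm),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d x %d voxels @ %.4f mm (%.2f x %.2f x %.2f mm)\n",
              x$dim[1], x$dim[2], x$dim[3], x$voxel_size_mm,
              x$extent_mm[1], x$extent_mm[2], x$extent_mm[3]))
  invisible(x)
}

# mm -> 1-based voxel index along one axis, clipped into the grid
mm_to_voxel <- function(pos_mm, voxel_size_mm, n) {
  pmin(pmax(floor(pos_mm / voxel_size_mm) + 1L, 1L), n)
}

# center coordinate (mm) of 1-based voxel indices
voxel_center_mm <- function(idx, voxel_size_mm) {
  (idx - 0.5) * voxel_size_mm
}
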