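# Internal 3-D filtering helpers wrapping the compiled kernels.

# integer offsets of a spherical structuring element of radius r voxels;
# a small tolerance keeps a nominally integer radius (e.g. 2 computed as
# a ratio of voxel sizes) from spilling into the next shell
sphere_offsets <- function(r) {
  stopifnot(r > 0)
  rmax <- as.integer(ceiling(r - 1e-9))
  g <- as.matrix(expand.grid(-rmax:rmax, -rmax:rmax, -rmax:rmax))
  g <- g[rowSums(g^2) <= r^2 + 1e-9 & rowSums(abs(g)) > 0, , drop = FALSE]
  storage.mode(g) <- "integer"
  g
}

gauss3 <- function(arr, sigma, normalize = FALSE) {
  d <- dim(arr)
  array(gaussian_filter3(as.numeric(arr), as.integer(d), sigma, normalize), d)
}

med3 <- function(arr, ksize = 3) {
  d <- dim(arr)
  array(median_filter3(as.numeric(arr), as.integer(d), as.integer(ksize)), d)
}

# greyscale opening with a spherical element
grey_open3 <- function(arr, radius) {
  d <- dim(arr)
  offs <- sphere_offsets(radius)
  er <- grey_morph3(as.numeric(arr), as.integer(d), offs, FALSE)
  array(grey_morph3(er, as.integer(d), offs, TRUE), d)
}

# white top-hat: input minus its opening
white_tophat3 <- function(arr, radius) {
  arr - grey_open3(arr, radius)
}

# binary dilation with a spherical element
binary_dilate3 <- function(arr, radius) {
  d <- dim(arr)
  out <- grey_morph3(as.numeric(arr != 0), as.integer(d),
                     sphere_offsets(radius), TRUE)
  array(out != 0, d)
}
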