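#' Branching parameters for the synthetic vessel generator
#'
#' @param levels Number of bifurcation generations per tree.
#' @param root_radius_mm Range the root vessel radius is drawn from, mm.
#' @param radius_decay Multiplicative radius shrink per generation.
#' @param root_length_frac Root segment length as a fraction of the
#'   smallest domain extent.
#' @param length_decay Multiplicative length shrink per generation.
#' @param direction_jitter Standard deviation of the random perturbation
#'   added to the parent direction at each bifurcation (unitless).
#' @return A list of class `branching_params`.
#' @export
branching_params <- function(levels = 4,
                             root_radius_mm = c(0.05, 0.09),
                             radius_decay = 0.78,
                             root_length_frac = 0.22,
                             length_decay = 0.8,
                             direction_jitter = 0.6) {
  stopifnot(levels >= 1, all(root_radius_mm > 0), radius_decay > 0,
            radius_decay <= 1, root_length_frac > 0, length_decay > 0)
  structure(list(levels = levels, root_radius_mm = root_radius_mm,
                 radius_decay = radius_decay,
                 root_length_frac = root_length_frac,
                 length_decay = length_decay,
                 direction_jitter = direction_jitter),
            class = "branching_params")
}

#' Generate a synthetic bilateral cerebral vessel network
#'
#' Grows random binary branching trees in the left hemisphere of a boxed
#' domain and (optionally) mirrors every segment across the lateral
#' midline, emulating the near-bilateral organization of the rodent brain
#' vasculature. An optional dominant midline vessel mimics the superior
#' sagittal sinus. Segment centerline speeds are drawn within
#' `speed_range`, larger vessels faster, covering the healthy regime of
#' roughly 1-30 mm/s.
#'
#' Axes are ordered (depth, lateral, elevation); the sagittal symmetry
#' plane sits at half the lateral extent.
#'
#' @param domain_extent 3-vector, mm: (depth, lateral, elevation) box size.
#' @param n_trees Number of arterial trees grown per hemisphere.
#' @param branching A [branching_params()] list.
#' @param speed_range Length-2 vector, mm/s; all segment speeds fall inside.
#' @param mirror If `TRUE`, every left-hemisphere segment gets an exact
#'   lateral mirror image so the lesion-free network is bilaterally
#'   symmetric by construction.
#' @param sinus If `TRUE`, add a midline vessel running along the
#'   elevation axis at shallow depth.
#' @param seed Integer RNG seed; the same seed reproduces the network
#'   bit-identically.
#' @return A `vessel_network`: a tibble of segments (one row each, with
#'   start/end coordinates in mm, `radius_mm`, `speed_mm_s`, `hemisphere`
#'   and `tree_id`) carrying `domain_extent` and `midline_mm` attributes.
#' @examples
#' net <- generate_vessel_network(seed = 1)
#' dplyr::count(net, hemisphere)
#' @export
generate_vessel_network <- function(domain_extent = c(6.3, 6.3, 6.3),
                                    n_trees = 6,
                                    branching = branching_params(),
                                    speed_range = c(1, 30),
                                    mirror = TRUE,
                                    sinus = TRUE,
                                    seed = 1) {
  stopifnot(length(domain_extent) == 3, n_trees >= 1,
            length(speed_range) == 2, speed_range[1] <= speed_range[2],
            all(speed_range >= 0), all(speed_range <= 100))
  margin <- 0.1
  root_len <- branching$root_length_frac * min(domain_extent)
  if (any(domain_extent <= 2 * margin + 0.1) || root_len < 0.05) {
    stop("generate_vessel_network: domain_extent ",
         paste(domain_extent, collapse = " x "),
         " mm is too small to contain a vessel segment (needs > ",
         2 * margin + 0.1, " mm per axis)")
  }
  midline <- domain_extent[2] / 2
  x_hi <- if (mirror) midline else domain_extent[2] - margin

  segs <- with_seed(seed, {
    out <- vector("list", n_trees)
    for (t in seq_len(n_trees)) {
      out[[t]] <- grow_tree(t, domain_extent, margin, x_hi, branching)
    }
    dplyr::bind_rows(out)
  })
  if (nrow(segs) == 0) stop("generate_vessel_network: no segments generated")

  # radius -> speed: larger vessels carry faster flow; uniform spread below
  segs <- with_seed(seed + 1000L, {
    r <- segs$radius_mm
    frac <- (r - min(r)) / max(max(r) - min(r), 1e-12)
    lo <- speed_range[1]
    hi <- speed_range[1] + frac * diff(speed_range)
    segs$speed_mm_s <- lo + (hi - lo) * runif(nrow(segs))^0.5
    segs
  })
  segs$hemisphere <- "left"

  if (mirror) {
    right <- segs
    right$x0_mm <- 2 * midline - segs$x0_mm
    right$x1_mm <- 2 * midline - segs$x1_mm
    right$hemisphere <- "right"
    segs <- dplyr::bind_rows(segs, right)
  }
  if (sinus) {
    sr <- 0.12
    segs <- dplyr::bind_rows(segs, tibble::tibble(
      tree_id = 0L,
      z0_mm = 0.15 * domain_extent[1], x0_mm = midline, y0_mm = margin,
      z1_mm = 0.15 * domain_extent[1], x1_mm = midline,
      y1_mm = domain_extent[3] - margin,
      radius_mm = sr,
      speed_mm_s = speed_range[1] + 0.9 * diff(speed_range),
      hemisphere = "midline"
    ))
  }
  segs$segment_id <- seq_len(nrow(segs))
  segs <- dplyr::relocate(segs, "segment_id")
  new_vessel_network(segs, domain_extent, midline)
}

new_vessel_network <- function(segments, domain_extent, midline_mm) {
  structure(
    tibble::new_tibble(segments, nrow = nrow(segments),
                       class = "vessel_network"),
    domain_extent = domain_extent,
    midline_mm = midline_mm
  )
}

# grow one binary tree confined to x in [margin, x_hi]
grow_tree <- function(tree_id, extent, margin, x_hi, bp) {
  clampv <- function(p) {
    pmin(pmax(p, c(margin, margin, margin)),
         c(extent[1] - margin, x_hi, extent[3] - margin))
  }
  root <- c(runif(1, 0.1, 0.35) * extent[1],
            runif(1, margin, max(x_hi - 0.2, margin + 0.01)),
            runif(1, 0.15, 0.85) * extent[3])
  dir0 <- c(runif(1, 0.5, 1), runif(1, -0.6, 0.6), runif(1, -0.6, 0.6))
  dir0 <- dir0 / sqrt(sum(dir0^2))
  r0 <- runif(1, bp$root_radius_mm[1], bp$root_radius_mm[2])
  len0 <- bp$root_length_frac * min(extent)

  rows <- list()
  queue <- list(list(p = root, d = dir0, lvl = 1L, r = r0, len = len0))
  while (length(queue) > 0) {
    nd <- queue[[1]]; queue <- queue[-1]
    q <- clampv(nd$p + nd$d * nd$len)
    if (sqrt(sum((q - nd$p)^2)) >= 0.05) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        tree_id = tree_id,
        z0_mm = nd$p[1], x0_mm = nd$p[2], y0_mm = nd$p[3],
        z1_mm = q[1], x1_mm = q[2], y1_mm = q[3],
        radius_mm = nd$r
      )
      if (nd$lvl < bp$levels) {
        for (child in 1:2) {
          d <- nd$d + bp$direction_jitter * rnorm(3)
          d <- d / sqrt(sum(d^2))
          queue[[length(queue) + 1L]] <- list(
            p = q, d = d, lvl = nd$lvl + 1L,
            r = nd$r * bp$radius_decay, len = nd$len * bp$length_decay)
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Tumor lesion specification
#'
#' Models a glioblastoma-like lesion: an (av)ascular core in which a
#' fraction of vessels drop out, surrounded by a periphery in which
#' surviving vessels are remodeled to the very slow flow regime reported
#' for this tumor model (0.1-0.8 mm/s versus ~1-30 mm/s in healthy
#' tissue).
#'
#' @param center 3-vector, mm: (depth, lateral, elevation) lesion center.
#' @param core_radius Radius of the dropout core, mm.
#' @param periphery_radius Radius of the slow-flow periphery, mm
#'   (`>= core_radius`).
#' @param periphery_speed_range Length-2 vector, mm/s, for resampled
#'   peripheral speeds.
#' @param dropout_fraction Fraction of core segments removed, in `[0, 1]`.
#' @return A list of class `tumor_spec`.
#' @export
tumor_spec <- function(center,
                       core_radius = 1,
                       periphery_radius = 2,
                       periphery_speed_range = c(0.1, 0.8),
                       dropout_fraction = 0.8) {
  stopifnot(length(center) == 3, core_radius >= 0,
            periphery_radius >= core_radius,
            length(periphery_speed_range) == 2,
            all(periphery_speed_range >= 0),
            periphery_speed_range[1] <= periphery_speed_range[2],
            dropout_fraction >= 0, dropout_fraction <= 1)
  structure(list(center = center, core_radius = core_radius,
                 periphery_radius = periphery_radius,
                 periphery_speed_range = periphery_speed_range,
                 dropout_fraction = dropout_fraction),
            class = "tumor_spec")
}

#' Apply a tumor lesion to a vessel network
#'
#' Removes a seeded random fraction of the segments whose midpoint lies in
#' the lesion core and resamples the centerline speed of surviving
#' segments within the periphery into the tumor's slow-flow range.
#' Segments outside the periphery are untouched.
#'
#' @param network A `vessel_network` from [generate_vessel_network()].
#' @param tumor A [tumor_spec()].
#' @param seed Integer RNG seed for the dropout draw and speed resampling.
#' @return The lesioned `vessel_network`.
#' @examples
#' net <- generate_vessel_network(seed = 1)
#' tum <- tumor_spec(center = c(3, 1.7, 3.15))
#' lesioned <- apply_tumor_model(net, tum, seed = 2)
#' @export
apply_tumor_model <- function(network, tumor, seed = 1) {
  stopifnot(inherits(tumor, "tumor_spec"))
  extent <- attr(network, "domain_extent")
  if (any(tumor$center < 0) || any(tumor$center > extent)) {
    stop("apply_tumor_model: tumor center must lie inside the domain")
  }
  mid <- cbind((network$z0_mm + network$z1_mm) / 2,
               (network$x0_mm + network$x1_mm) / 2,
               (network$y0_mm + network$y1_mm) / 2)
  d <- sqrt(colSums((t(mid) - tumor$center)^2))
  in_core <- d <= tumor$core_radius
  in_periph <- d <= tumor$periphery_radius

  with_seed(seed, {
    idx_core <- which(in_core)
    n_drop <- round(tumor$dropout_fraction * length(idx_core))
    drop <- if (n_drop > 0) sample(idx_core, n_drop) else integer(0)
    keep <- setdiff(seq_len(nrow(network)), drop)
    segs <- network[keep, , drop = FALSE]
    slow <- in_periph[keep]
    if (any(slow)) {
      segs$speed_mm_s[slow] <- runif(sum(slow),
                                     tumor$periphery_speed_range[1],
                                     tumor$periphery_speed_range[2])
    }
    new_vessel_network(segs, extent, attr(network, "midline_mm"))
  })
}

#' Mirror a network across the sagittal midline
#'
#' Reflects every segment's lateral coordinate about the symmetry plane.
#' On a lesion-free network generated with `mirror = TRUE` this returns
#' the same segment set (up to ordering), which is what makes the
#' rasterized centerlines of network and reflection identical.
#'
#' @param network A `vessel_network`.
#' @return The reflected `vessel_network`.
#' @export
mirror_network <- function(network) {
  m <- attr(network, "midline_mm")
  out <- network
  out$x0_mm <- 2 * m - network$x0_mm
  out$x1_mm <- 2 * m - network$x1_mm
  out$hemisphere <- c(left = "right", right = "left",
                      midline = "midline")[network$hemisphere]
  out
}

#' Rasterize vessel centerlines (or tubes) onto a voxel grid
#'
#' Marks every voxel traversed by a segment centerline; with
#' `as_tubes = TRUE`, marks every voxel whose center lies within the
#' segment radius of the centerline, producing finite-width vessels.
#'
#' @param network A `vessel_network`.
#' @param voxel_size_mm Isotropic raster voxel, mm.
#' @param as_tubes Rasterize finite-radius tubes instead of centerlines.
#' @return A binary 3-D array covering the network domain.
#' @export
rasterize_network <- function(network, voxel_size_mm, as_tubes = FALSE) {
  extent <- attr(network, "domain_extent")
  dims <- pmax(as.integer(round(extent / voxel_size_mm)), 1L)
  vol <- array(0L, dims)
  if (nrow(network) == 0) return(vol)
  p0 <- cbind(network$z0_mm, network$x0_mm, network$y0_mm)
  p1 <- cbind(network$z1_mm, network$x1_mm, network$y1_mm)
  lens <- sqrt(rowSums((p1 - p0)^2))
  step <- voxel_size_mm / 4
  nstep <- pmax(ceiling(lens / step), 1L) + 1L
  seg_of <- rep.int(seq_len(nrow(network)), nstep)
  tt <- sequence(nstep, from = 0L) / (nstep[seg_of] - 1L)
  pts <- p0[seg_of, , drop = FALSE] +
    (p1 - p0)[seg_of, , drop = FALSE] * tt
  if (!as_tubes) {
    idx <- cbind(mm_to_voxel(pts[, 1], voxel_size_mm, dims[1]),
                 mm_to_voxel(pts[, 2], voxel_size_mm, dims[2]),
                 mm_to_voxel(pts[, 3], voxel_size_mm, dims[3]))
    vol[idx] <- 1L
    return(vol)
  }
  # tubes: stamp a ball of the segment radius at each sample point,
  # selecting voxels by center-to-point distance (symmetric under
  # lateral reflection for mirrored networks)
  radius <- network$radius_mm[seg_of]
  rv <- ceiling(max(network$radius_mm) / voxel_size_mm)
  offs <- as.matrix(expand.grid(-rv:rv, -rv:rv, -rv:rv))
  for (o in seq_len(nrow(offs))) {
    ctr <- floor(pts / voxel_size_mm) + 1L
    idx <- ctr + rep(offs[o, ], each = nrow(ctr))
    ok <- idx[, 1] >= 1 & idx[, 1] <= dims[1] &
      idx[, 2] >= 1 & idx[, 2] <= dims[2] &
      idx[, 3] >= 1 & idx[, 3] <= dims[3]
    cmm <- (idx - 0.5) * voxel_size_mm
    d2 <- rowSums((cmm - pts)^2)
    ok <- ok & d2 <= radius^2
    if (any(ok)) vol[idx[ok, , drop = FALSE]] <- 1L
  }
  vol
}
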