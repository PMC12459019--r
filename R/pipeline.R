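#' Pipeline configuration
#'
#' One object holding every stage's parameters for [run_pipeline()].
#' The acquisition geometry defaults to the 7.81 MHz sequence
#' ([acquisition_params()]): half-wavelength beamforming voxels and
#' 500 vps. The synthetic stage defaults describe the study conditions:
#' healthy centerline speeds of 1-30 mm/s, about 80 bubbles per volume,
#' static high-amplitude tissue clutter, and (for lesioned runs) a tumor
#' with an 80 % dropout core and a 0.1-0.8 mm/s slow-flow periphery.
#'
#' @param grid_dim Beamformed grid voxel counts (depth, lateral,
#'   elevation).
#' @param n_volumes Number of volumes to simulate/process.
#' @param n_trees Arterial trees per hemisphere in the synthetic network.
#' @param speed_range Healthy centerline speed range, mm/s.
#' @param mean_mb_per_volume Target bubbles per volume.
#' @param tissue_amplitude,noise_sigma Clutter and noise levels of the
#'   synthetic stack, in bubble-peak units.
#' @param tumor `NULL` for a control run or a [tumor_spec()].
#' @param batch_size,discard_fraction Clutter-filter batching.
#' @param localization A [localization_config()].
#' @param tracking A [tracking_config()].
#' @param render_voxel_mm Render grid voxel, mm. The acquisition-scale default
#'   is \eqn{\lambda/20}; end-to-end synthetic runs use \eqn{\lambda/10}
#'   to keep the render grid tractable.
#' @param shell_radii,shell_thickness Shell geometry for the hemodynamic
#'   profile, mm.
#' @param shell_center_mm Optional fixed tumoral-side point (depth,
#'   lateral, elevation, mm) for the shell analysis; paired control/GBM
#'   runs should share it (the implant-site reference). When `NULL` the
#'   point is derived from the run itself (tumor center, or the
#'   left-hemisphere support centroid, at the reference depth 3 mm below
#'   the top of the vascular support).
#' @param center_frequency,sound_speed,volume_rate Acquisition constants.
#' @param seed Master seed; every stochastic stage derives its own
#'   sub-seed from it.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(grid_dim = c(48, 48, 48),
                            n_volumes = 800,
                            n_trees = 5,
                            speed_range = c(1, 30),
                            mean_mb_per_volume = 90,
                            tissue_amplitude = 10,
                            noise_sigma = 0.01,
                            tumor = NULL,
                            batch_size = 200,
                            discard_fraction = 0.10,
                            localization = localization_config(),
                            tracking = tracking_config(),
                            render_voxel_mm = wavelength_mm() / 10,
                            shell_radii = seq(0.25, 4, by = 0.25),
                            shell_thickness = 0.25,
                            shell_center_mm = NULL,
                            center_frequency = 7.81e6,
                            sound_speed = 1540,
                            volume_rate = 500,
                            seed = 1) {
  lambda <- wavelength_mm(center_frequency, sound_speed)
  structure(list(
    grid_dim = as.integer(grid_dim), n_volumes = as.integer(n_volumes),
    n_trees = n_trees, speed_range = speed_range,
    mean_mb_per_volume = mean_mb_per_volume,
    tissue_amplitude = tissue_amplitude, noise_sigma = noise_sigma,
    tumor = tumor, batch_size = batch_size,
    discard_fraction = discard_fraction,
    localization = localization, tracking = tracking,
    render_voxel_mm = render_voxel_mm,
    shell_radii = shell_radii, shell_thickness = shell_thickness,
    shell_center_mm = shell_center_mm,
    center_frequency = center_frequency, sound_speed = sound_speed,
    volume_rate = volume_rate, voxel_size_mm = lambda / 2,
    wavelength_mm = lambda, seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full synthetic ULM pipeline
#'
#' simulate -> SVD filter -> localize -> track -> render -> metrics, all
#' from one [pipeline_config()]. Deterministic for a fixed seed.
#'
#' @param config A [pipeline_config()].
#' @param keep_stack Keep the (large) filtered stack in the result.
#' @param verbose Emit a message per stage.
#' @return A list of class `ulm_result`: `network`, `truth`,
#'   `localizations`, `tracks`, `image` ([render_density()]),
#'   `velocity` (median-filtered [render_velocity()]), and `metrics`
#'   (an `ulm_metrics` report with `vd`, `bs` and the shell-profile
#'   tibble `lhr`).
#' @examples
#' \donttest{
#' cfg <- pipeline_config(grid_dim = c(32, 32, 32), n_volumes = 100,
#'                        n_trees = 3, seed = 1)
#' res <- run_pipeline(cfg)
#' glance(res$metrics)
#' }
#' @export
run_pipeline <- function(config = pipeline_config(), keep_stack = FALSE,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message("run_pipeline: ", ...)
  # a failing stage is reported by name
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("run_pipeline: stage '", name, "' failed: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  cfg_hash <- rlang::hash(config)
  seed <- config$seed
  grid <- grid_spec(config$grid_dim, config$voxel_size_mm)
  extent <- grid$extent_mm

  say("generating vessel network")
  network <- stage("simulate", generate_vessel_network(
    domain_extent = extent, n_trees = config$n_trees,
    speed_range = config$speed_range, mirror = TRUE, sinus = TRUE,
    seed = seed))
  if (!is.null(config$tumor)) {
    say("applying tumor model")
    network <- stage("simulate",
                     apply_tumor_model(network, config$tumor,
                                       seed = seed + 1L))
  }

  say("simulating microbubble transits")
  truth <- stage("simulate", simulate_mb_transits(
    network, n_volumes = config$n_volumes,
    volume_rate = config$volume_rate,
    mean_mb_per_volume = config$mean_mb_per_volume, seed = seed + 2L))

  # synthesize -> filter -> localize streamed batch-by-batch so only one
  # batch of volumes is ever held in memory
  tissue <- if (config$tissue_amplitude > 0) {
    with_seed(seed + 3L, tissue_field(grid$dim, config$tissue_amplitude))
  } else NULL
  starts <- seq(1L, config$n_volumes, by = config$batch_size)
  locs <- vector("list", length(starts))
  stack <- NULL
  for (b in seq_along(starts)) {
    s0 <- starts[b]
    e0 <- min(s0 + config$batch_size - 1L, config$n_volumes)
    say("batch ", b, "/", length(starts), " (volumes ", s0, "-", e0,
        "): synthesize + SVD filter + localize")
    bt <- stage("synthesize", synthesize_volume_stack(
      truth, grid, tissue_amplitude = config$tissue_amplitude,
      noise_sigma = config$noise_sigma, volume_rate = config$volume_rate,
      center_frequency = config$center_frequency,
      sound_speed = config$sound_speed, seed = seed + 100L + b,
      frames = s0:e0, tissue = tissue))
    k <- max(1L, round(config$discard_fraction * (e0 - s0 + 1L)))
    bt <- stage("filter", svd_filter_batch(bt, k = k))
    lb <- stage("localize", localize_stack(bt, config$localization,
                                           batch_size = config$batch_size))
    lb$volume_index <- lb$volume_index + s0 - 1L
    locs[[b]] <- lb
    if (keep_stack) {
      if (is.null(stack)) {
        stack <- bt
        stack$data <- array(0, c(grid$dim, config$n_volumes))
      }
      stack$data[, , , s0:e0] <- bt$data
    }
    rm(bt)
  }
  locs <- dplyr::bind_rows(locs)

  say("tracking (", nrow(locs), " localizations)")
  tracks <- stage("track",
                  track_microbubbles(locs, config$tracking,
                                     config$volume_rate))

  say("rendering (", dplyr::n_distinct(tracks$track_id), " tracks)")
  image <- stage("render",
                 render_density(tracks, extent, config$render_voxel_mm))
  vmap <- stage("render",
                render_velocity(tracks, extent, config$render_voxel_mm))
  vmap <- stage("render", median_filter_velocity(vmap))

  say("computing biomarkers")
  metrics <- stage("metrics", compute_metrics(image, vmap, config))
  metrics$config_hash <- cfg_hash

  structure(list(config = config, network = network, truth = truth,
                 stack = stack, localizations = locs, tracks = tracks,
                 image = image, velocity = vmap, metrics = metrics),
            class = "ulm_result", config_hash = cfg_hash)
}

# the three biomarkers from rendered volumes
compute_metrics <- function(image, vmap, config) {
  skel <- skeletonize_ulm(image)
  dims <- dim(image$density)
  roi <- roi_hemisphere(dims, image$render_voxel_mm, "left")
  vd <- vascular_density(skel, roi, image$render_voxel_mm)
  bs <- bilateral_symmetry(image, wavelength = config$wavelength_mm)
  ctr <- shell_center(image, config)
  sspec <- shell_spec(ctr, midline_mm = image$extent_mm[2] / 2,
                      radii = config$shell_radii,
                      thickness = config$shell_thickness)
  lhr <- shell_profiles(vmap, sspec)
  structure(list(vd = vd, bs = as.numeric(bs), lhr = lhr,
                 shell_center_left = ctr,
                 bs_alignment = attributes(bs)),
            class = "ulm_metrics")
}

# tumoral-side point of interest: the tumor center when one is modeled;
# otherwise the left-hemisphere centroid at the reference depth. The
# axial coordinate is 3 mm below the top of the vascular support (the
# synthetic stand-in for "below the skull surface").
shell_center <- function(image, config) {
  if (!is.null(config$shell_center_mm)) return(config$shell_center_mm)
  supp <- which(image$counts > 0)
  d <- dim(image$counts)
  v <- image$render_voxel_mm
  if (length(supp) == 0) {
    return(c(d[1] / 2, d[2] / 4, d[3] / 2) * v)
  }
  idx <- arrayInd(supp, d)
  z_top <- (min(idx[, 1]) - 0.5) * v
  z_ref <- min(z_top + 3, (d[1] - 0.5) * v)
  if (!is.null(config$tumor)) {
    ctr <- config$tumor$center
    return(c(z_ref, ctr[2], ctr[3]))
  }
  left <- idx[(idx[, 2] - 0.5) * v < d[2] * v / 2, , drop = FALSE]
  if (nrow(left) == 0) left <- idx
  c(z_ref, mean(left[, 2] - 0.5) * v, mean(left[, 3] - 0.5) * v)
}

#' @export
print.ulm_metrics <- function(x, ...) {
  cat("<ulm_metrics>\n")
  cat(sprintf("  vascular density (VD): %.2f centerline voxels / mm^3\n", x$vd))
  cat(sprintf("  bilateral symmetry (BS): %.3f\n", x$bs))
  ok <- !is.na(x$lhr$difference)
  if (any(ok)) {
    cat(sprintf("  hemisphere speed difference (LHR): %.2f to %.2f mm/s over r = %.2f-%.2f mm\n",
                min(x$lhr$difference[ok]), max(x$lhr$difference[ok]),
                min(x$lhr$radius_mm), max(x$lhr$radius_mm)))
  }
  invisible(x)
}

#' @export
print.ulm_result <- function(x, ...) {
  cat(sprintf("<ulm_result> %d localizations, %d tracks\n",
              nrow(x$localizations),
              dplyr::n_distinct(x$tracks$track_id)))
  print(x$metrics)
  invisible(x)
}

#' Tidy the shell-profile biomarker of a metrics report
#'
#' @param x An `ulm_metrics` object.
#' @param ... Unused.
#' @return The per-shell tibble (`radius_mm`, left/right mean speeds,
#'   `difference`, supported voxel counts).
#' @exportS3Method generics::tidy
#' @export
tidy.ulm_metrics <- function(x, ...) x$lhr

#' One-row summary of a metrics report
#'
#' @param x An `ulm_metrics` object.
#' @param ... Unused.
#' @return Tibble with `vd`, `bs`, and the minimum and mean hemisphere
#'   speed difference across shells.
#' @exportS3Method generics::glance
#' @export
glance.ulm_metrics <- function(x, ...) {
  ok <- !is.na(x$lhr$difference)
  tibble::tibble(
    vd = x$vd, bs = x$bs,
    min_difference = if (any(ok)) min(x$lhr$difference[ok]) else NA_real_,
    mean_difference = if (any(ok)) mean(x$lhr$difference[ok]) else NA_real_
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Small deterministic test fixtures
#'
#' Three miniature stacks with attached ground truth, built in code:
#' `static_tissue` (tissue and noise only, no bubbles),
#' `single_bubble` (one bubble at constant speed on a noiseless
#' background), and `symmetric_network` (a mirror-symmetric two-
#' hemisphere network with clutter). Each element holds `$stack`
#' (at most 32^3 voxels by 50 frames), plus the generating objects.
#'
#' @param seed Integer seed.
#' @return Named list of fixtures.
#' @export
make_fixtures <- function(seed = 1) {
  grid <- grid_spec(c(32, 32, 32), wavelength_mm() / 2)
  empty_truth <- structure(
    tibble::tibble(bubble_id = integer(), segment_id = integer(),
                   volume_index = integer(), z_mm = numeric(),
                   x_mm = numeric(), y_mm = numeric(),
                   true_speed_mm_s = numeric()),
    n_volumes = 50L, volume_rate = 500)

  static_tissue <- list(
    truth = empty_truth,
    stack = synthesize_volume_stack(empty_truth, grid,
                                    tissue_amplitude = 10,
                                    noise_sigma = 0.01, seed = seed))

  net1 <- single_segment_network(grid$extent_mm, speed = 10)
  truth1 <- simulate_mb_transits(net1, n_volumes = 50,
                                 mean_mb_per_volume = 1,
                                 radial_jitter = FALSE, seed = seed + 1L)
  single_bubble <- list(
    network = net1, truth = truth1,
    stack = synthesize_volume_stack(truth1, grid, tissue_amplitude = 0,
                                    noise_sigma = 0, seed = seed + 1L))

  net2 <- generate_vessel_network(domain_extent = grid$extent_mm,
                                  n_trees = 3, mirror = TRUE,
                                  seed = seed + 2L)
  truth2 <- simulate_mb_transits(net2, n_volumes = 50,
                                 mean_mb_per_volume = 20, seed = seed + 2L)
  symmetric_network <- list(
    network = net2, truth = truth2,
    stack = synthesize_volume_stack(truth2, grid, tissue_amplitude = 10,
                                    noise_sigma = 0.01, seed = seed + 2L))

  list(static_tissue = static_tissue, single_bubble = single_bubble,
       symmetric_network = symmetric_network)
}

# one straight segment through the middle of the domain
single_segment_network <- function(extent, speed = 10, radius = 0.05) {
  segs <- tibble::tibble(
    segment_id = 1L, tree_id = 1L,
    z0_mm = extent[1] / 2, x0_mm = 0.15 * extent[2], y0_mm = extent[3] / 2,
    z1_mm = extent[1] / 2, x1_mm = 0.85 * extent[2], y1_mm = extent[3] / 2,
    radius_mm = radius, speed_mm_s = speed, hemisphere = "left")
  new_vessel_network(segs, extent, extent[2] / 2)
}
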