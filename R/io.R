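#' Write / read a volume stack as NIfTI
#'
#' The 4-D intensity array is stored as one NIfTI file with the voxel
#' size (mm) and volume period (s) in the header; acquisition constants
#' travel in a JSON sidecar next to the image.
#'
#' @param stack A [volume_stack()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_stack_nifti <- function(stack, path) {
  stopifnot(inherits(stack, "volume_stack"))
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_stack_nifti requires the RNifti package")
  }
  img <- RNifti::asNifti(stack$data)
  RNifti::pixdim(img) <- c(rep(stack$voxel_size_mm, 3), 1 / stack$volume_rate)
  RNifti::writeNifti(img, path)
  meta <- list(voxel_size_mm = stack$voxel_size_mm,
               volume_rate = stack$volume_rate,
               center_frequency = stack$center_frequency,
               sound_speed = stack$sound_speed,
               dim = dim(stack$data))
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_stack_nifti
#' @return For `read_stack_nifti`, the [volume_stack()].
#' @export
read_stack_nifti <- function(path) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("read_stack_nifti requires the RNifti package")
  }
  img <- RNifti::readNifti(path)
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  volume_stack(array(as.numeric(img), dim(img)),
               voxel_size_mm = meta$voxel_size_mm,
               volume_rate = meta$volume_rate,
               center_frequency = meta$center_frequency,
               sound_speed = meta$sound_speed)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Write / read tabular pipeline artifacts as CSV with a JSON sidecar
#'
#' Vessel networks, ground-truth records, localizations and tracks are
#' plain tibbles; they are stored as CSV (one row per record) plus a JSON
#' sidecar holding their attributes (domain extent, midline, volume
#' count).
#'
#' @param x A tibble (possibly a `vessel_network` or ground-truth table).
#' @param path Output `.csv` path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  extras <- attributes(x)
  extras <- extras[setdiff(names(extras),
                           c("names", "row.names", "class"))]
  if (length(extras) > 0) {
    jsonlite::write_json(extras, paste0(sub("\\.csv$", "", path), ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_records_csv
#' @param vessel_network Read back as a `vessel_network` (restores the
#'   domain attributes).
#' @return For `read_records_csv`, the tibble.
#' @export
read_records_csv <- function(path, vessel_network = FALSE) {
  df <- tibble::as_tibble(utils::read.csv(path))
  side <- paste0(sub("\\.csv$", "", path), ".json")
  extras <- if (file.exists(side)) {
    jsonlite::read_json(side, simplifyVector = TRUE)
  } else list()
  if (vessel_network) {
    return(new_vessel_network(df, extras$domain_extent, extras$midline_mm))
  }
  for (nm in names(extras)) attr(df, nm) <- extras[[nm]]
  df
}

#' Write a metrics report as JSON (plus the per-shell CSV)
#'
#' @param metrics An `ulm_metrics` object.
#' @param path Output `.json` path; the shell profile goes to the same
#'   stem with `_shells.csv`.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  stopifnot(inherits(metrics, "ulm_metrics"))
  jsonlite::write_json(
    list(vd = metrics$vd, bs = metrics$bs,
         shell_center_left = metrics$shell_center_left,
         config_hash = metrics$config_hash),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(as.data.frame(metrics$lhr),
                   paste0(sub("\\.json$", "", path), "_shells.csv"),
                   row.names = FALSE)
  invisible(path)
}
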