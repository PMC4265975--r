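#' Write temperature maps as NIfTI with a JSON sidecar
#'
#' One volume per dynamic (2D maps are stacked along the third dimension);
#' the sidecar records timestamps and dynamic numbers.
#'
#' @param maps list of `temperature_map`s (or `temperature_field`s).
#' @param path output path without extension; writes `<path>.nii.gz` and
#'   `<path>.json`.
#' @param pixel_mm pixel size recorded in the header (mm).
#' @return Invisibly, the NIfTI path.
#' @export
write_temperature_nifti <- function(maps, path, pixel_mm = 1) {
  if (inherits(maps, "temperature_map") || inherits(maps, "temperature_field")) {
    maps <- list(maps)
  }
  get_mat <- function(m) {
    if (inherits(m, "temperature_map")) {
      v <- m$delta_t_c; v[!m$valid] <- 0; v
    } else m$values
  }
  vols <- lapply(maps, get_mat)
  arr <- simplify2array(vols)
  img <- RNifti::asNifti(arr, pixdim = rep(pixel_mm, min(3, length(dim(arr)))))
  nii_path <- paste0(path, ".nii.gz")
  RNifti::writeNifti(img, nii_path)
  times <- vapply(maps, function(m)
    (m$time_s %||% NA_real_), numeric(1))
  dyns <- vapply(maps, function(m)
    as.integer(m$dynamic %||% NA_integer_), integer(1))
  jsonlite::write_json(
    list(n_volumes = length(maps), time_s = times, dynamic = dyns,
         pixel_mm = pixel_mm),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(nii_path)
}

#' Write an image frame as NIfTI magnitude/phase pair with JSON sidecar
#'
#' @param frame an `image_frame`.
#' @param path output path without extension; writes `<path>_mag.nii.gz`,
#'   `<path>_phase.nii.gz` and `<path>.json`.
#' @export
write_frame_nifti <- function(frame, path) {
  RNifti::writeNifti(RNifti::asNifti(simplify2array(frame$magnitude)),
                     paste0(path, "_mag.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(frame$phase_rad),
                     paste0(path, "_phase.nii.gz"))
  jsonlite::write_json(
    list(image_type = frame$image_type, stack_id = frame$stack_id,
         slice = frame$slice, dynamic = frame$dynamic,
         acq_time_s = frame$acq_time_s,
         te_ms = frame$seq$te_ms, tr_ms = frame$seq$tr_ms,
         dynamic_time_s = frame$seq$dynamic_time_s,
         center_mm = frame$geometry$center_mm),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write per-element scan records as CSV
#'
#' Columns `element_id`, `summary_amplitude_pa`, `time_s`.
#'
#' @param records data frame of scan records.
#' @param path CSV path.
#' @export
write_scan_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read a run configuration from JSON or YAML
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return Named list of configuration overrides.
#' @export
read_run_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  }
}
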