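#' Read and write CT volumes and label maps as NIfTI-1
#'
#' CT volumes are stored as int16 HU, label maps as uint8 with a JSON label
#' dictionary sidecar (`<file>.labels.json`). Voxel spacing travels in the
#' NIfTI pixdim; the axis convention (medial-lateral, anterior-posterior,
#' superior-inferior with slices increasing distally) is fixed
#' package-wide.
#'
#' @param ct A [ct_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return The path, invisibly.
#' @export
write_ct_nifti <- function(ct, path) {
  stopifnot(inherits(ct, "ct_volume"))
  img <- RNifti::asNifti(unclass(ct))
  RNifti::pixdim(img) <- spacing_mm(ct)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_ct_nifti
#' @export
read_ct_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  ct_volume(array(as.integer(img), dim(img)), RNifti::pixdim(img)[1:3])
}

#' @rdname write_ct_nifti
#' @param labels A [label_map()].
#' @export
write_labels_nifti <- function(labels, path) {
  stopifnot(inherits(labels, "label_map"))
  img <- RNifti::asNifti(unclass(labels))
  RNifti::pixdim(img) <- spacing_mm(labels)
  RNifti::writeNifti(img, path, datatype = "uint8")
  jsonlite::write_json(as.list(label_codes),
                       paste0(sub("\\.nii(\\.gz)?$", "", path), ".labels.json"),
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ct_nifti
#' @export
read_labels_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  label_map(array(as.integer(img), dim(img)), RNifti::pixdim(img)[1:3])
}

#' Read and write landmarks as JSON
#'
#' @param landmarks A [tibial_landmarks()].
#' @param path JSON path.
#' @return The path (write) or a [tibial_landmarks()] (read).
#' @export
write_landmarks_json <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "tibial_landmarks"))
  jsonlite::write_json(unclass(landmarks), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_landmarks_json
#' @export
read_landmarks_json <- function(path) {
  lm <- jsonlite::read_json(path)
  lm <- lapply(lm, function(v) if (is.null(v)) NA_real_ else as.numeric(v))
  do.call(tibial_landmarks, lm)
}

#' Pipeline configuration
#'
#' Validated bundle of the tunable analysis parameters. Unknown keys are
#' rejected. `landmarks` may carry per-knee overrides (a list of
#' [tibial_landmarks()] keyed by knee id) or a single `tubercle_z` /
#' `tubercle_below_cut_mm` default.
#'
#' @param thresholds A [threshold_set()].
#' @param cement_adjacency_mm Cement-implant adjacency in mm.
#' @param closing_radius_voxels Bone-envelope closing radius in voxels.
#' @param min_involvement_cm3 AORI involvement threshold in cm^3.
#' @param tubercle_below_cut_mm Default tubercle depth below the cut, used
#'   when no explicit tubercle landmark is supplied.
#' @param seed Integer seed for any stochastic step.
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(thresholds = threshold_set(),
                            cement_adjacency_mm = 3,
                            closing_radius_voxels = 3,
                            min_involvement_cm3 = 0.5,
                            tubercle_below_cut_mm = 40,
                            seed = 1L) {
  if (cement_adjacency_mm < 0 || closing_radius_voxels < 0 ||
      min_involvement_cm3 < 0 || tubercle_below_cut_mm <= 0)
    abort("Config parameters out of range.")
  structure(list(thresholds = thresholds,
                 cement_adjacency_mm = cement_adjacency_mm,
                 closing_radius_voxels = closing_radius_voxels,
                 min_involvement_cm3 = min_involvement_cm3,
                 tubercle_below_cut_mm = tubercle_below_cut_mm,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts the keys of [pipeline_config()] plus a `thresholds` block of HU
#' intervals (`defect`, `bone`, `cement`, `implant`). Unknown keys are an
#' error.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("thresholds", "cement_adjacency_mm", "closing_radius_voxels",
             "min_involvement_cm3", "tubercle_below_cut_mm", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad) > 0)
    abort(paste("Unknown config keys:", paste(bad, collapse = ", ")))
  if (!is.null(y$thresholds)) y$thresholds <- do.call(threshold_set, y$thresholds)
  do.call(pipeline_config, y)
}
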