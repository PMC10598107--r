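#' AORI grade display names
#'
#' Ordinal coding of the Anderson Orthopaedic Research Institute tibial
#' bone-loss scale: I = 1, IIa = 2, IIb = 3, III = 4.
#'
#' @param grade Integer vector of grades in 1..4.
#' @return Character vector of display names.
#' @export
aori_label <- function(grade) {
  stopifnot(all(grade %in% 1:4))
  c("I", "IIa", "IIb", "III")[grade]
}

#' Grade a segmented defect on the AORI scale
#'
#' Pure geometric grading of the defect class (implant and cement excluded)
#' against two transverse planes:
#' * type III (4): defect volume distal to the tibial tubercle plane exceeds
#'   `min_involvement_cm3` (component subsidence, the clinical alternative
#'   criterion, is not inferable from a static preoperative image);
#' * type II: defect volume distal to the fibular-tip plane exceeds the
#'   threshold -- IIb (3) when both the medial and the lateral condyle each
#'   exceed it there, IIa (2) otherwise;
#' * type I (1): no supra-threshold defect crosses the fibular-tip plane.
#'
#' "Distal to" a plane means slice index strictly greater than the landmark
#' slice. The condyles are split by the sagittal plane at
#' `landmarks$midline_x`.
#'
#' @param labels A [label_map()].
#' @param landmarks A [tibial_landmarks()]; `fibular_tip_z` and `tubercle_z`
#'   are required.
#' @param min_involvement_cm3 Minimal defect volume (cm^3) that counts as
#'   involvement; the default 0.5 suppresses single-voxel noise.
#' @return Integer grade 1-4 with attribute `label`.
#' @export
grade_defect <- function(labels, landmarks, min_involvement_cm3 = 0.5) {
  stopifnot(inherits(labels, "label_map"), inherits(landmarks, "tibial_landmarks"))
  if (min_involvement_cm3 < 0) abort("`min_involvement_cm3` must be >= 0.")
  if (is.na(landmarks$fibular_tip_z))
    abort("`fibular_tip_z` is required to grade (type-II plane undefined).")
  if (is.na(landmarks$tubercle_z))
    abort("`tubercle_z` is required to grade (type-III plane undefined).")
  arr <- unclass(labels)
  v <- voxel_cm3(labels)
  d <- dim(arr)
  def <- arr == label_codes[["defect"]]
  if (!any(def)) return(structure(1L, label = "I", class = "aori_grade"))

  idx <- which(def, arr.ind = TRUE)
  z0 <- idx[, 3] - 1L
  x0 <- idx[, 1] - 1L

  below_tub <- sum(z0 > landmarks$tubercle_z) * v
  if (below_tub > min_involvement_cm3)
    return(structure(4L, label = "III", class = "aori_grade"))

  distal <- z0 > landmarks$fibular_tip_z
  v_med <- sum(distal & x0 < landmarks$midline_x) * v
  v_lat <- sum(distal & x0 >= landmarks$midline_x) * v
  if (v_med + v_lat > min_involvement_cm3) {
    g <- if (v_med > min_involvement_cm3 && v_lat > min_involvement_cm3) 3L else 2L
    return(structure(g, label = aori_label(g), class = "aori_grade"))
  }
  structure(1L, label = "I", class = "aori_grade")
}

#' @export
print.aori_grade <- function(x, ...) {
  cat(sprintf("AORI %s (%d)\n", attr(x, "label"), as.integer(x)))
  invisible(x)
}

#' Grade a cohort of segmented knees
#'
#' Element-wise [grade_defect()]; order-preserving. Per-knee failures are
#' re-thrown with the knee identifier.
#'
#' @param label_maps List of [label_map()]s.
#' @param landmark_list List of [tibial_landmarks()], same length.
#' @param min_involvement_cm3 Passed to [grade_defect()].
#' @return Integer vector of grades (named by knee if `label_maps` is named).
#' @export
grade_cohort <- function(label_maps, landmark_list, min_involvement_cm3 = 0.5) {
  if (length(label_maps) != length(landmark_list))
    abort("`label_maps` and `landmark_list` must have equal length.")
  ids <- names(label_maps) %||% as.character(seq_along(label_maps))
  out <- integer(length(label_maps))
  for (i in seq_along(label_maps)) {
    g <- tryCatch(
      grade_defect(label_maps[[i]], landmark_list[[i]], min_involvement_cm3),
      error = function(e) abort(sprintf("Knee %s: %s", ids[i], conditionMessage(e))))
    out[i] <- as.integer(g)
  }
  names(out) <- if (!is.null(names(label_maps))) ids else NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
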