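#' Anatomical landmarks of the proximal tibia
#'
#' All slice coordinates are 0-based indices along the superior-inferior axis
#' (axis 3; increasing distally); `midline_x` is a (possibly fractional)
#' 0-based voxel coordinate along the mediolateral axis separating the medial
#' (smaller x) from the lateral condyle. `distal_end_z` is exclusive: the ROI
#' is the half-open slice range `[tibial_cut_z, distal_end_z)`.
#'
#' @param tibial_cut_z Slice of the tibial resection plane (top of the tray).
#' @param fibular_tip_z Most proximal fibular slice (AORI type-II plane).
#' @param fibular_widest_z Slice of maximal fibular mediolateral width
#'   (epiphysis-metaphysis junction).
#' @param tubercle_z Slice of the tibial tubercle level (AORI type-III
#'   plane); supplied, not detected from image content.
#' @param midline_x Mediolateral coordinate splitting the condyles.
#' @param distal_end_z Exclusive end slice of the depicted tibia.
#' @return A `tibial_landmarks` list.
#' @export
tibial_landmarks <- function(tibial_cut_z, fibular_tip_z, fibular_widest_z,
                             tubercle_z, midline_x, distal_end_z) {
  lm <- list(tibial_cut_z = as.numeric(tibial_cut_z),
             fibular_tip_z = as.numeric(fibular_tip_z),
             fibular_widest_z = as.numeric(fibular_widest_z),
             tubercle_z = as.numeric(tubercle_z),
             midline_x = as.numeric(midline_x),
             distal_end_z = as.numeric(distal_end_z))
  if (!is.na(lm$fibular_widest_z)) {
    if (!(lm$tibial_cut_z < lm$fibular_widest_z &&
          lm$fibular_widest_z < lm$distal_end_z))
      abort("Landmarks must be ordered tibial_cut_z < fibular_widest_z < distal_end_z.")
    if (!is.na(lm$fibular_tip_z) && lm$fibular_tip_z > lm$fibular_widest_z)
      abort("`fibular_tip_z` must not lie distal to `fibular_widest_z`.")
  }
  structure(lm, class = "tibial_landmarks")
}

#' @export
print.tibial_landmarks <- function(x, ...) {
  cat("<tibial_landmarks> (0-based slice indices)\n")
  for (nm in names(x)) cat(sprintf("  %-17s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Detect the tibial cut plane
#'
#' The most proximal slice containing implant voxels (the tray defines the
#' resection level); if no implant is present, the most proximal slice
#' containing tibial bone.
#'
#' @param labels A [label_map()].
#' @return 0-based slice index.
#' @export
detect_tibial_cut <- function(labels) {
  imp <- apply(unclass(labels) == label_codes[["implant"]], 3, any)
  if (any(imp)) return(which(imp)[1] - 1L)
  bone <- apply(unclass(labels) == label_codes[["bone_tibia"]], 3, any)
  if (!any(bone)) abort("Empty volume: no implant or tibial bone voxels.")
  which(bone)[1] - 1L
}

# per-slice fibular ML extent; ties broken proximally
fibula_extent_by_slice <- function(lab, sp) {
  fib <- unclass(lab) == label_codes[["bone_fibula"]]
  sl <- which(apply(fib, 3, any))
  ext <- vapply(sl, function(k) {
    xs <- which(apply(fib[, , k, drop = FALSE], 1, any))
    (max(xs) - min(xs) + 1) * sp[1]
  }, numeric(1))
  list(tip_z = sl[1] - 1L,
       widest_z = sl[which.max(ext)] - 1L,
       slices = sl - 1L, extent_mm = ext)
}

#' Detect fibular landmarks
#'
#' Tip = most proximal fibular slice; widest = slice maximizing the fibular
#' mediolateral extent in mm (ties broken by the most proximal slice).
#'
#' @param labels A [label_map()] with a `bone_fibula` class.
#' @return List with `fibular_tip_z` and `fibular_widest_z` (0-based).
#' @export
detect_fibular_landmarks <- function(labels) {
  if (!any(unclass(labels) == label_codes[["bone_fibula"]]))
    abort(paste("No fibula in the label map; supply `fibular_tip_z` and",
                "`fibular_widest_z` explicitly via tibial_landmarks()."))
  fl <- fibula_extent_by_slice(labels, spacing_mm(labels))
  list(fibular_tip_z = fl$tip_z, fibular_widest_z = fl$widest_z)
}

#' Measure the widest epiphyseal mediolateral width
#'
#' Maximum over slices in the half-open range `[cut_z, widest_z)` of the
#' tibial foreground (tibial bone, cement, implant, defect; fibula excluded)
#' mediolateral extent, `(max - min + 1) * spacing` in mm.
#'
#' @param labels A [label_map()].
#' @param cut_z,widest_z 0-based slice bounds (cut inclusive, widest
#'   exclusive).
#' @return Width in mm.
#' @export
measure_epiphysis_width <- function(labels, cut_z, widest_z) {
  arr <- unclass(labels)
  ks <- slice_seq(c(cut_z, widest_z), dim(arr)[3])
  if (length(ks) == 0L) abort("Empty epiphyseal slice range.")
  fg_codes <- label_codes[c("bone_tibia", "cement", "implant", "defect")]
  sp <- spacing_mm(labels)
  w <- 0
  for (k in ks) {
    m <- arr[, , k] %in% fg_codes
    if (any(m)) {
      xs <- which(apply(matrix(m, dim(arr)[1]), 1, any))
      w <- max(w, (max(xs) - min(xs) + 1) * sp[1])
    }
  }
  if (w == 0) abort("No tibial foreground in the epiphyseal slice range.")
  w
}

#' Partition the tibial ROI into zonal-fixation zones
#'
#' Implements the rule of the square: the epiphysis runs from the tibial cut
#' to the widest fibular-head level; the metaphyseal-diaphyseal junction lies
#' one epiphyseal width W below the cut (the square's top edge is anchored at
#' the cut plane), clamped to the end of the depicted tibia; the diaphysis is
#' the remainder.
#'
#' @param landmarks A [tibial_landmarks()].
#' @param width_mm The measured widest epiphyseal width W (square side).
#' @param spacing Voxel spacing (length 3; slice spacing is `spacing[3]`).
#' @return A `zone_partition`: half-open 0-based slice ranges `epiphysis`,
#'   `metaphysis`, `diaphysis`, plus `square_side_mm`.
#' @export
partition_zones <- function(landmarks, width_mm, spacing) {
  stopifnot(inherits(landmarks, "tibial_landmarks"))
  if (!is.finite(width_mm) || width_mm <= 0) abort("`width_mm` must be > 0.")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  cut <- landmarks$tibial_cut_z
  widest <- landmarks$fibular_widest_z
  dend <- landmarks$distal_end_z
  if (is.na(widest)) abort("`fibular_widest_z` is required to partition zones.")
  meta_dia <- min(cut + round(width_mm / spacing[3]), dend)
  if (meta_dia <= widest)
    warn("Square shorter than the epiphysis: metaphysis is empty.")
  meta_dia <- max(meta_dia, widest)
  structure(list(epiphysis = c(cut, widest),
                 metaphysis = c(widest, meta_dia),
                 diaphysis = c(meta_dia, dend),
                 square_side_mm = width_mm),
            class = "zone_partition")
}

#' @export
print.zone_partition <- function(x, ...) {
  cat(sprintf("<zone_partition> square side %.1f mm\n", x$square_side_mm))
  for (z in c("epiphysis", "metaphysis", "diaphysis"))
    cat(sprintf("  %-10s [%d, %d)\n", z, x[[z]][1], x[[z]][2]))
  invisible(x)
}

#' Detect all tibial landmarks from a label map
#'
#' Combines [detect_tibial_cut()], [detect_fibular_landmarks()], the distal
#' ROI end, and the condylar midline (the mediolateral centroid of tibial
#' bone in the diaphysis, falling back to all tibial bone when the square
#' reaches the end of the volume). The tibial tubercle level cannot be
#' detected from image content and must be supplied.
#'
#' @param labels A [label_map()] (after [split_tibia_fibula()]).
#' @param tubercle_z 0-based tubercle slice; required for AORI type-III
#'   grading.
#' @return A [tibial_landmarks()].
#' @export
detect_landmarks <- function(labels, tubercle_z = NA) {
  arr <- unclass(labels)
  cut <- detect_tibial_cut(labels)
  fib <- detect_fibular_landmarks(labels)
  fg_codes <- label_codes[c("bone_tibia", "cement", "implant", "defect")]
  fg <- apply(array(arr %in% fg_codes, dim(arr)), 3, any)
  dend <- max(which(fg))           # 0-based exclusive end
  w <- measure_epiphysis_width(labels, cut, fib$fibular_widest_z)
  sp <- spacing_mm(labels)
  meta_dia <- min(cut + round(w / sp[3]), dend)
  ks <- slice_seq(c(meta_dia, dend), dim(arr)[3])
  bone <- arr == label_codes[["bone_tibia"]]
  sub <- if (length(ks) > 0 && any(bone[, , ks])) bone[, , ks, drop = FALSE] else bone
  xw <- apply(sub, 1, sum)
  midline <- sum((seq_len(dim(arr)[1]) - 1L) * xw) / sum(xw)
  tibial_landmarks(cut, fib$fibular_tip_z, fib$fibular_widest_z,
                   tubercle_z, midline, dend)
}
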