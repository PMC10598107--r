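#' Tissue label codes
#'
#' Integer codes used in every label map produced or consumed by the package.
#' Axis convention for all volumes: axis 1 runs medial to lateral, axis 2
#' anterior to posterior, and axis 3 superior to inferior, so the slice index
#' along axis 3 increases distally. Slice indices exposed in landmarks and
#' zone partitions are 0-based with half-open ranges; physical position =
#' index times spacing.
#'
#' @format Named integer vector with elements `background` (0), `bone_tibia`
#'   (1), `bone_fibula` (2), `cement` (3), `implant` (4), `defect` (5).
#' @export
label_codes <- c(
  background = 0L, bone_tibia = 1L, bone_fibula = 2L,
  cement = 3L, implant = 4L, defect = 5L
)

#' Construct a CT volume
#'
#' Wraps a 3D array of Hounsfield units with its voxel spacing. HU values are
#' clamped by validation to the calibrated CT range \[-1024, 3071\].
#'
#' @param voxels 3D numeric/integer array of HU values.
#' @param spacing_mm Numeric length-3, voxel size per axis in mm
#'   (medial-lateral, anterior-posterior, superior-inferior).
#' @return A `ct_volume` object (the array with `spacing_mm` attribute).
#' @export
ct_volume <- function(voxels, spacing_mm) {
  if (length(dim(voxels)) != 3L) abort("`voxels` must be a 3D array.")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (length(spacing_mm) != 3L || any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    abort("`spacing_mm` must be 3 strictly positive values.")
  rng <- range(voxels)
  if (rng[1] < -1024 || rng[2] > 3071)
    abort("HU values must lie in [-1024, 3071].")
  structure(voxels, spacing_mm = spacing_mm, class = "ct_volume")
}

#' Construct a label map
#'
#' @param labels 3D integer array of tissue codes (see [label_codes]).
#' @param spacing_mm Voxel spacing in mm (recycled to length 3).
#' @return A `label_map` object.
#' @export
label_map <- function(labels, spacing_mm) {
  if (length(dim(labels)) != 3L) abort("`labels` must be a 3D array.")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) == 1L) spacing_mm <- rep(spacing_mm, 3L)
  if (!all(labels %in% label_codes))
    abort("Unknown label code in `labels`.")
  storage.mode(labels) <- "integer"
  structure(labels, spacing_mm = spacing_mm, class = "label_map")
}

#' Voxel spacing of a volume or label map
#' @param x A `ct_volume` or `label_map`.
#' @return Numeric length-3 spacing in mm.
#' @export
spacing_mm <- function(x) attr(x, "spacing_mm")

#' Voxel volume in cubic centimetres
#' @param x A `ct_volume` or `label_map`, or a length-3 spacing vector.
#' @return Volume of one voxel in cm^3.
#' @export
voxel_cm3 <- function(x) {
  sp <- if (is.numeric(x) && is.null(dim(x))) x else spacing_mm(x)
  prod(sp) / 1000
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm, HU range [%d, %d]\n",
              d[1], d[2], d[3], paste(signif(spacing_mm(x), 4), collapse = " x "),
              as.integer(min(x)), as.integer(max(x))))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<label_map> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(spacing_mm(x), 4), collapse = " x ")))
  cnt <- tabulate(as.integer(x) + 1L, nbins = 6L)
  for (i in seq_along(label_codes))
    cat(sprintf("  %-11s %d\n", names(label_codes)[i], cnt[i]))
  invisible(x)
}

#' Per-class voxel counts of a label map
#'
#' @param labels A `label_map`.
#' @param z0_range Optional half-open 0-based slice range `c(from, to)` along
#'   the superior-inferior axis restricting the tally.
#' @return Named integer vector over the six classes.
#' @export
label_counts <- function(labels, z0_range = NULL) {
  arr <- unclass(labels)
  if (!is.null(z0_range)) {
    z1 <- slice_seq(z0_range, dim(arr)[3])
    arr <- arr[, , z1, drop = FALSE]
  }
  cnt <- tabulate(as.integer(arr) + 1L, nbins = 6L)
  setNames(cnt, names(label_codes))
}

# 1-based R slice indices for a 0-based half-open [from, to) range; empty
# ranges give integer(0)
slice_seq <- function(z0_range, nz) {
  from <- max(0L, as.integer(z0_range[1]))
  to <- min(as.integer(z0_range[2]), nz)
  if (to <= from) return(integer(0))
  seq.int(from + 1L, to)
}
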