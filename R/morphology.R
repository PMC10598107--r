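#' Euclidean distance transform
#'
#' Distance from every voxel to the nearest `TRUE` voxel of a mask, computed
#' with a separable exact algorithm on the squared distances. Spacing-aware:
#' distances are physical when `spacing` is the voxel size in mm; pass
#' `spacing = c(1, 1, 1)` for voxel-index distances.
#'
#' @param mask 3D logical array.
#' @param spacing Per-axis step (length 3 or scalar).
#' @param squared Return squared distances (default `FALSE`).
#' @return Numeric array of distances; `Inf` where the mask is empty.
#' @export
distance_to <- function(mask, spacing = c(1, 1, 1), squared = FALSE) {
  d <- dim(mask)
  if (length(d) != 3L) abort("`mask` must be a 3D array.")
  spacing <- rep(as.numeric(spacing), length.out = 3L)
  out <- .edt_sq_cpp(as.logical(mask), as.integer(d), spacing)
  if (!squared) out <- sqrt(out)
  out
}

#' Morphological ball operations on 3D masks
#'
#' Dilation, erosion and closing with a Euclidean ball of radius `r`, derived
#' from the distance transform. `spacing` chooses the metric: unit spacing
#' gives a radius in voxels, physical spacing a radius in mm.
#'
#' @param mask 3D logical array.
#' @param r Ball radius (same units as `spacing`).
#' @param spacing Per-axis step, default voxel units.
#' @return Logical array of the same shape.
#' @export
dilate_ball <- function(mask, r, spacing = c(1, 1, 1)) {
  if (r <= 0) return(mask)
  distance_to(mask, spacing, squared = TRUE) <= r^2
}

#' @rdname dilate_ball
#' @export
erode_ball <- function(mask, r, spacing = c(1, 1, 1)) {
  if (r <= 0) return(mask)
  distance_to(!mask, spacing, squared = TRUE) > r^2
}

#' @rdname dilate_ball
#' @export
close_ball <- function(mask, r, spacing = c(1, 1, 1)) {
  if (r <= 0) return(mask)
  erode_ball(dilate_ball(mask, r, spacing), r, spacing)
}

#' Fill internal cavities of a 3D mask
#'
#' Adds every background component that does not touch the volume border
#' (air fully enclosed by the mask) to the mask.
#'
#' @param mask 3D logical array.
#' @return Logical array with internal holes filled.
#' @export
fill_holes <- function(mask) {
  comp <- connected_components(!mask)
  nc <- max(comp)
  if (nc == 0L) return(mask)
  d <- dim(comp)
  border <- unique(c(comp[c(1, d[1]), , ], comp[, c(1, d[2]), ],
                     comp[, , c(1, d[3])]))
  internal <- setdiff(seq_len(nc), border)
  if (length(internal) > 0) mask[comp %in% internal] <- TRUE
  mask
}

#' Label connected components of a 3D mask
#'
#' 26-connectivity; components are numbered by decreasing voxel count
#' (label 1 is the largest), 0 is background.
#'
#' @param mask 3D logical array.
#' @return Integer array of component labels.
#' @export
connected_components <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3L) abort("`mask` must be a 3D array.")
  .label_components_cpp(as.logical(mask), as.integer(d))
}
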