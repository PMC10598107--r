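#' Hounsfield-unit threshold set
#'
#' Closed HU intervals for the four tissue classes. Defaults are the
#' periprosthetic tibia thresholds: defect \[-1024, 200\], bone \[200, 1800\],
#' cement \[300, 1400\], implant \[2000, 3071\]. A voxel at exactly 200 HU
#' (shared by the defect and bone ranges) is assigned to bone, the
#' conservative choice that avoids overestimating defect size.
#'
#' @param defect,bone,cement,implant Length-2 numeric HU intervals.
#' @return A `threshold_set`.
#' @export
threshold_set <- function(defect = c(-1024, 200), bone = c(200, 1800),
                          cement = c(300, 1400), implant = c(2000, 3071)) {
  thr <- list(defect = as.numeric(defect), bone = as.numeric(bone),
              cement = as.numeric(cement), implant = as.numeric(implant))
  for (nm in names(thr))
    if (length(thr[[nm]]) != 2L || diff(thr[[nm]]) <= 0)
      abort(sprintf("Threshold `%s` must be an increasing HU interval.", nm))
  if (thr$implant[1] <= thr$bone[2] && thr$bone[1] <= thr$implant[2])
    abort("Implant and bone HU ranges must be disjoint.")
  structure(thr, class = "threshold_set")
}

#' Segment a CT volume by HU thresholds
#'
#' Voxel classification with explicit rules for the ambiguous HU ranges:
#' * implant: HU in the implant range;
#' * the unassigned gap between the bone and implant ranges (1800-2000 HU by
#'   default) goes to implant within one voxel of the implant mask (a
#'   partial-volume rim at the bone-metal interface, which would otherwise
#'   read as osteolysis), else to bone;
#' * cement: HU in the cement range *and* within `cement_adjacency_mm`
#'   (Euclidean, via the distance transform) of the implant -- a cement
#'   mantle is by definition at the bone-implant interface, so cement wins
#'   over bone only in that shell;
#' * bone: remaining voxels in the bone range (a voxel at the shared 200 HU
#'   boundary is bone, not defect);
#' * defect: voxels in the defect range lying inside the morphological
#'   closing (ball radius `closing_radius_voxels`) of the bone/cement/implant
#'   envelope; defect-range voxels outside the envelope are exterior air.
#'
#' The single bone class can then be split into tibia and fibula with
#' [split_tibia_fibula()].
#'
#' @param ct A [ct_volume()].
#' @param thresholds A [threshold_set()].
#' @param cement_adjacency_mm Maximum distance from the implant at which
#'   cement-range HU is called cement (default 3 mm).
#' @param closing_radius_voxels Ball radius (in voxels) of the closing that
#'   defines the bone envelope containing defects (default 3).
#' @return A [label_map()] with all bone in `bone_tibia`.
#' @export
segment_hu <- function(ct, thresholds = threshold_set(),
                       cement_adjacency_mm = 3, closing_radius_voxels = 3) {
  stopifnot(inherits(ct, "ct_volume"))
  if (cement_adjacency_mm < 0) abort("`cement_adjacency_mm` must be >= 0.")
  thr <- thresholds
  hu <- unclass(ct)
  sp <- spacing_mm(ct)

  implant <- hu >= thr$implant[1] & hu <= thr$implant[2]
  # unassigned gap between bone and implant ranges
  gap <- hu > thr$bone[2] & hu < thr$implant[1]
  if (any(implant)) {
    near_imp <- dilate_ball(implant, 1.8)  # one-voxel 26-neighbourhood shell
    implant <- implant | (gap & near_imp)
    gap_bone <- gap & !near_imp
  } else {
    gap_bone <- gap
  }

  cement_range <- hu >= thr$cement[1] & hu <= thr$cement[2] & !implant
  if (any(implant)) {
    d_imp <- distance_to(implant, sp, squared = TRUE)
    cement <- cement_range & d_imp <= cement_adjacency_mm^2
  } else {
    warn("Empty implant mask: cement class is empty by construction.")
    cement <- array(FALSE, dim(hu))
  }

  bone <- ((hu >= thr$bone[1] & hu <= thr$bone[2]) | gap_bone) &
    !implant & !cement

  solid <- bone | cement | implant
  if (!any(solid)) abort("No foreground: volume contains no bone, cement or implant.")
  # the bone envelope: closing bridges narrow surface openings (the stand-in
  # for manual refinement), hole filling captures fully enclosed cavities --
  # an osteolytic void deeper than the closing ball is still a defect
  envelope <- fill_holes(close_ball(solid, closing_radius_voxels))
  defect <- hu >= thr$defect[1] & hu < thr$bone[1] & envelope

  lab <- array(0L, dim(hu))
  lab[bone] <- label_codes[["bone_tibia"]]
  lab[cement] <- label_codes[["cement"]]
  lab[implant] <- label_codes[["implant"]]
  lab[defect] <- label_codes[["defect"]]
  label_map(lab, sp)
}

#' Split the bone class into tibia and fibula
#'
#' Connected components of the bone class (26-connectivity). The largest
#' component is the tibia; the largest remaining component whose mediolateral
#' centroid is lateral to (greater than) the tibial centroid is the fibula.
#' Any other component within 2 voxels of the tibia is merged into it,
#' otherwise it is dropped to background. When two candidate components tie
#' in size, the one with more voxels in the proximal half of the volume is
#' the tibia.
#'
#' @param labels A [label_map()] whose bone is all in `bone_tibia`.
#' @return A [label_map()] with `bone_tibia` and `bone_fibula` separated.
#' @export
split_tibia_fibula <- function(labels) {
  arr <- unclass(labels)
  bone <- arr == label_codes[["bone_tibia"]] | arr == label_codes[["bone_fibula"]]
  if (!any(bone)) abort("No bone voxels to split.")
  comp <- connected_components(bone)
  ncomp <- max(comp)
  out <- arr
  if (ncomp == 1L) {
    out[bone] <- label_codes[["bone_tibia"]]
    return(label_map(out, spacing_mm(labels)))
  }
  sizes <- tabulate(comp[comp > 0L], nbins = ncomp)
  tib_id <- 1L
  if (ncomp >= 2L && sizes[2] == sizes[1]) {
    # size tie: more voxels in the proximal half wins
    nz <- dim(arr)[3]
    prox <- function(id) sum(comp[, , seq_len(nz %/% 2)] == id)
    if (prox(2L) > prox(1L)) tib_id <- 2L
  }
  cx <- function(id) {
    m <- comp == id
    xw <- apply(m, 1, sum)
    sum(seq_along(xw) * xw) / sum(xw)
  }
  tib_cx <- cx(tib_id)
  fib_id <- 0L
  for (id in setdiff(order(sizes, decreasing = TRUE), tib_id)) {
    if (cx(id) > tib_cx) { fib_id <- id; break }
  }
  d_tib <- distance_to(comp == tib_id, c(1, 1, 1), squared = TRUE)
  for (id in seq_len(ncomp)) {
    m <- comp == id
    if (id == tib_id) {
      out[m] <- label_codes[["bone_tibia"]]
    } else if (id == fib_id) {
      out[m] <- label_codes[["bone_fibula"]]
    } else if (min(d_tib[m]) <= 4) {  # within 2 voxels of the tibia
      out[m] <- label_codes[["bone_tibia"]]
    } else {
      out[m] <- label_codes[["background"]]
    }
  }
  label_map(out, spacing_mm(labels))
}
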