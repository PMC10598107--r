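#' Specify an ellipsoidal bone defect for a phantom
#'
#' Defects are carved out of tibial bone as ellipsoids. Either give an
#' explicit centre and semi-axes, or a `zone_target`/`side` pair and let
#' [generate_phantom()] place the defect at a canonical position inside that
#' zone. When `target_volume_cm3` is supplied the semi-axes are rescaled
#' isotropically so the analytic ellipsoid volume (4/3 pi abc) equals the
#' target.
#'
#' @param zone_target One of `"epiphysis"`, `"metaphysis"`, `"diaphysis"`;
#'   used for automatic placement when `centre_mm` is `NULL`.
#' @param side One of `"medial"`, `"lateral"`, `"both"`, `"central"`.
#'   `"both"` carves two mirrored ellipsoids, one per condyle.
#' @param semi_axes_mm Length-3 ellipsoid semi-axes in mm (ML, AP, SI).
#' @param centre_mm Optional explicit centre (physical mm).
#' @param target_volume_cm3 Optional target analytic volume in cm^3.
#' @return A `defect_spec` list.
#' @export
defect_spec <- function(zone_target = "metaphysis", side = "medial",
                        semi_axes_mm = c(6, 5, 8), centre_mm = NULL,
                        target_volume_cm3 = NULL) {
  zone_target <- match.arg(zone_target, c("epiphysis", "metaphysis", "diaphysis"))
  side <- match.arg(side, c("medial", "lateral", "both", "central"))
  semi_axes_mm <- as.numeric(semi_axes_mm)
  if (length(semi_axes_mm) != 3L || any(semi_axes_mm <= 0))
    abort("`semi_axes_mm` must be 3 positive lengths.")
  if (!is.null(target_volume_cm3)) {
    if (target_volume_cm3 <= 0) abort("`target_volume_cm3` must be positive.")
    v0 <- 4 / 3 * pi * prod(semi_axes_mm) / 1000
    semi_axes_mm <- semi_axes_mm * (target_volume_cm3 / v0)^(1 / 3)
  }
  structure(list(zone_target = zone_target, side = side,
                 semi_axes_mm = semi_axes_mm, centre_mm = centre_mm,
                 target_volume_cm3 = target_volume_cm3),
            class = "defect_spec")
}

#' Analytic volume of a defect ellipsoid
#' @param d A `defect_spec`.
#' @return Volume in cm^3 (doubled for `side = "both"`).
#' @export
defect_volume_cm3 <- function(d) {
  v <- 4 / 3 * pi * prod(d$semi_axes_mm) / 1000
  if (d$side == "both") 2 * v else v
}

#' Specify a periprosthetic tibial CT phantom
#'
#' Describes the geometry and imaging conditions of a synthetic proximal
#' tibia with an implanted tibial component: stacked elliptical bone
#' cross-sections with a wide epiphyseal flare tapering into a cylindrical
#' shaft, a separate fibula with an ellipsoidal head, a cemented tray + stem
#' implant, optional ellipsoidal defects, additive Gaussian HU noise and
#' optional radial metal-streak artifacts. The slice spacing default is
#' 0.625 mm, the acquisition used by the pipeline this emulates.
#'
#' @param grid_shape Integer length-3 voxel counts per axis.
#' @param spacing_mm Voxel size per axis in mm.
#' @param epiphysis_width_mm Widest mediolateral extent of the proximal tibia.
#' @param shaft_radius_mm Mediolateral semi-axis of the diaphyseal shaft.
#' @param total_length_mm Length of bone from the tibial cut to the most
#'   distal depicted slice.
#' @param flare_length_mm Length below the cut over which the epiphyseal
#'   width is held constant before tapering.
#' @param taper_frac Fraction of `total_length_mm` over which the flare
#'   tapers (quadratically) to the shaft radius.
#' @param ap_ratio Anterior-posterior to mediolateral semi-axis ratio.
#' @param cut_mm Physical superior-inferior position of the tibial resection
#'   plane (bone begins here; the tray sits immediately above).
#' @param fibula `NULL` to omit the fibula, else a list with `gap_mm`
#'   (clearance between tibial surface and fibular head), `head_semi_mm`
#'   (head ellipsoid semi-axes), `head_below_cut_mm` (head centre depth below
#'   the cut; the head centre is the widest fibular level and the tip sits
#'   one SI semi-axis above it) and `shaft_radius_mm`.
#' @param implant `NULL` for no implant, else a list with `tray_thickness_mm`,
#'   `tray_coverage` (fraction of the cut cross-section covered),
#'   `stem_length_mm`, `stem_radius_mm`.
#' @param cement_thickness_mm Cement mantle thickness under the tray and
#'   around the stem.
#' @param tubercle_below_cut_mm Depth of the tibial tubercle plane below the
#'   cut (a supplied anatomical level, not detected from image content).
#' @param defects List of [defect_spec()] objects.
#' @param noise_sd_hu SD of additive Gaussian HU noise (0 = noise-free).
#' @param streak_artifacts Add radial high/low-HU streaks around the stem.
#' @param streak_amplitude_hu Peak streak amplitude in HU.
#' @param seed Integer seed; feeds only the noise and streak phase, so
#'   noise-free phantoms are identical across seeds.
#' @return A validated `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(152L, 112L, 176L),
                         spacing_mm = c(0.7, 0.7, 0.625),
                         epiphysis_width_mm = 70,
                         shaft_radius_mm = 12,
                         total_length_mm = 95,
                         flare_length_mm = 12,
                         taper_frac = 0.75,
                         ap_ratio = 0.8,
                         cut_mm = 8,
                         fibula = list(gap_mm = 10, head_semi_mm = c(8, 8, 10),
                                       head_below_cut_mm = 22, shaft_radius_mm = 5),
                         implant = list(tray_thickness_mm = 4, tray_coverage = 1,
                                        stem_length_mm = 25, stem_radius_mm = 5),
                         cement_thickness_mm = 3,
                         tubercle_below_cut_mm = 40,
                         defects = list(),
                         noise_sd_hu = 0,
                         streak_artifacts = FALSE,
                         streak_amplitude_hu = 300,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  spacing_mm <- rep(as.numeric(spacing_mm), length.out = 3L)
  stopifnot(length(grid_shape) == 3L)
  lens <- c(epiphysis_width_mm, shaft_radius_mm, total_length_mm,
            flare_length_mm, spacing_mm, cut_mm)
  if (any(!is.finite(lens)) || any(lens <= 0))
    abort("All phantom lengths and spacings must be strictly positive.")
  if (cement_thickness_mm < 0) abort("`cement_thickness_mm` must be >= 0.")
  if (noise_sd_hu < 0) abort("`noise_sd_hu` must be >= 0.")
  if (!is.null(implant) && implant$tray_thickness_mm < spacing_mm[3])
    abort("Grid too coarse: implant tray thinner than one slice.")
  if (shaft_radius_mm >= epiphysis_width_mm / 2)
    abort("`shaft_radius_mm` must be smaller than half the epiphyseal width.")
  if (inherits(defects, "defect_spec")) defects <- list(defects)
  if (!all(vapply(defects, inherits, TRUE, "defect_spec")))
    abort("`defects` must be a list of defect_spec objects.")
  spec <- list(grid_shape = grid_shape, spacing_mm = spacing_mm,
               epiphysis_width_mm = epiphysis_width_mm,
               shaft_radius_mm = shaft_radius_mm,
               total_length_mm = total_length_mm,
               flare_length_mm = flare_length_mm, taper_frac = taper_frac,
               ap_ratio = ap_ratio, cut_mm = cut_mm, fibula = fibula,
               implant = implant, cement_thickness_mm = cement_thickness_mm,
               tubercle_below_cut_mm = tubercle_below_cut_mm,
               defects = defects, noise_sd_hu = noise_sd_hu,
               streak_artifacts = streak_artifacts,
               streak_amplitude_hu = streak_amplitude_hu,
               seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

# mediolateral bone semi-axis at depth dz below the cut
tibia_semi_ml <- function(spec, dz) {
  w2 <- spec$epiphysis_width_mm / 2
  taper_len <- spec$taper_frac * spec$total_length_mm
  u <- pmin(pmax((dz - spec$flare_length_mm) /
                   pmax(taper_len - spec$flare_length_mm, 1e-9), 0), 1)
  spec$shaft_radius_mm + (w2 - spec$shaft_radius_mm) * (1 - u)^2
}

# geometric centres used for construction and automatic defect placement
phantom_frame <- function(spec) {
  w2 <- spec$epiphysis_width_mm / 2
  cx <- 4 + w2                       # 4 mm medial margin
  cy <- (spec$grid_shape[2] - 1) * spec$spacing_mm[2] / 2
  list(cx = cx, cy = cy,
       cut = spec$cut_mm,
       end = spec$cut_mm + spec$total_length_mm,
       fib_cx = if (is.null(spec$fibula)) NA_real_ else
         cx + w2 + spec$fibula$gap_mm + spec$fibula$head_semi_mm[1],
       fib_cz = if (is.null(spec$fibula)) NA_real_ else
         spec$cut_mm + spec$fibula$head_below_cut_mm)
}

# canonical centre for a defect placed by zone/side; the fibular tip plane
# sits one SI head semi-axis above the head centre
auto_defect_centre <- function(spec, d) {
  fr <- phantom_frame(spec)
  tip_dz <- if (is.null(spec$fibula)) 12 else
    spec$fibula$head_below_cut_mm - spec$fibula$head_semi_mm[3]
  meta_dia_dz <- spec$epiphysis_width_mm  # rule-of-the-square junction depth
  dz <- switch(d$zone_target,
    epiphysis  = (spec$cement_thickness_mm + tip_dz) / 2 + 1,
    metaphysis = (tip_dz + spec$tubercle_below_cut_mm) / 2 + 4,
    diaphysis  = meta_dia_dz + d$semi_axes_mm[3] + 2)
  stem_reach <- if (is.null(spec$implant)) 0 else
    spec$implant$stem_radius_mm + spec$cement_thickness_mm
  clear <- stem_reach * (dz < (if (is.null(spec$implant)) 0 else
                                 spec$implant$stem_length_mm + spec$cement_thickness_mm +
                                   d$semi_axes_mm[3]))
  x_off <- switch(d$side,
    medial  = -(clear + d$semi_axes_mm[1] + 1),
    lateral = clear + d$semi_axes_mm[1] + 1,
    both    = clear + d$semi_axes_mm[1] + 1,  # mirrored pair carved
    central = 0)
  c(fr$cx + x_off, fr$cy, fr$cut + dz)
}

#' Generate a synthetic periprosthetic tibial CT volume with ground truth
#'
#' Voxelizes the geometry in a [phantom_spec()] onto the requested grid and
#' returns both the HU volume and the exact per-voxel truth. Noise-free HU
#' values sit at the midpoint of each tissue's threshold interval (defect
#' -400, bone 1000, cement 850, implant 2500, air -1000), so every voxel's
#' clean HU lies strictly inside its class interval.
#'
#' @param spec A `phantom_spec`.
#' @return List with elements `ct` (a [ct_volume()]), and `truth`: a list of
#'   `labels` (a [label_map()]), `landmarks` (a [tibial_landmarks()]),
#'   `zone_volumes` (per-zone volume report computed from the true labels),
#'   and `grade` (true AORI grade, integer 1-4).
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  sp <- spec$spacing_mm
  nd <- spec$grid_shape
  fr <- phantom_frame(spec)
  x <- (seq_len(nd[1]) - 1L) * sp[1]
  y <- (seq_len(nd[2]) - 1L) * sp[2]
  z <- (seq_len(nd[3]) - 1L) * sp[3]
  if (fr$end > max(z))
    abort("Grid too short: tibia extends beyond the most distal slice.")

  imp <- spec$implant
  cem <- spec$cement_thickness_mm
  has_imp <- !is.null(imp)
  w2 <- spec$epiphysis_width_mm / 2
  if (has_imp) {
    tray_a <- imp$tray_coverage * w2
    tray_b <- imp$tray_coverage * spec$ap_ratio * w2
    if (fr$cut - imp$tray_thickness_mm < 0)
      abort("Grid too short proximally for the implant tray.")
  }

  fib <- spec$fibula
  has_fib <- !is.null(fib)
  if (has_fib) {
    fib_edge <- fr$fib_cx + fib$head_semi_mm[1]
    if (fib_edge > max(x))
      abort("Grid too narrow for the fibula.")
  }

  # resolve defect centres, then validate containment inside the bone envelope
  defs <- list()
  for (d in spec$defects) {
    ctr <- if (is.null(d$centre_mm)) auto_defect_centre(spec, d) else
      as.numeric(d$centre_mm)
    defs <- c(defs, list(list(centre = ctr, semi_axes_mm = d$semi_axes_mm)))
    if (d$side == "both") {
      mir <- c(2 * fr$cx - ctr[1], ctr[2], ctr[3])
      defs <- c(defs, list(list(centre = mir, semi_axes_mm = d$semi_axes_mm)))
    }
  }
  for (df in defs) {
    ax <- df$semi_axes_mm; ctr <- df$centre
    dzr <- c(ctr[3] - ax[3], ctr[3] + ax[3]) - fr$cut
    if (dzr[1] < 0 || dzr[2] > spec$total_length_mm)
      abort("Defect extends outside the bone envelope (superior-inferior).")
    # conservative in-plane check at SI stations: the bounding point of the
    # defect cross-section must stay inside the local bone ellipse
    for (dz in seq(dzr[1], dzr[2], length.out = 17)) {
      s <- sqrt(pmax(0, 1 - ((dz - (ctr[3] - fr$cut)) / ax[3])^2))
      a_loc <- tibia_semi_ml(spec, dz)
      b_loc <- spec$ap_ratio * a_loc
      if ((abs(ctr[1] - fr$cx) + s * ax[1])^2 / a_loc^2 +
          (abs(ctr[2] - fr$cy) + s * ax[2])^2 / b_loc^2 > 1)
        abort("Defect extends outside the bone envelope (in-plane).")
    }
  }

  lab <- array(0L, nd)
  X2c <- matrix((x - fr$cx)^2, nd[1], nd[2])
  Y2c <- matrix((y - fr$cy)^2, nd[1], nd[2], byrow = TRUE)
  R2 <- X2c + Y2c
  if (has_fib) Xf2 <- matrix((x - fr$fib_cx)^2, nd[1], nd[2])

  for (k in seq_len(nd[3])) {
    zk <- z[k]
    dz <- zk - fr$cut
    sl <- matrix(0L, nd[1], nd[2])
    if (zk >= fr$cut && zk < fr$end) {
      a <- tibia_semi_ml(spec, dz); b <- spec$ap_ratio * a
      inside <- X2c / a^2 + Y2c / b^2 <= 1
      sl[inside] <- 1L
      if (has_imp && dz < imp$stem_length_mm)
        sl[R2 <= imp$stem_radius_mm^2 & inside] <- 4L
      for (df in defs) {
        ax <- df$semi_axes_mm; ctr <- df$centre
        zz <- (zk - ctr[3]) / ax[3]
        if (abs(zz) <= 1) {
          lim <- 1 - zz^2
          Xd <- matrix((x - ctr[1])^2 / ax[1]^2, nd[1], nd[2])
          Yd <- matrix((y - ctr[2])^2 / ax[2]^2, nd[1], nd[2], byrow = TRUE)
          sl[Xd + Yd <= lim & sl == 1L] <- 5L
        }
      }
    } else if (has_imp && zk >= fr$cut - imp$tray_thickness_mm && zk < fr$cut) {
      tray_in <- X2c / tray_a^2 + Y2c / tray_b^2 <= 1
      sl[tray_in] <- 4L
    }
    if (has_fib && zk >= fr$fib_cz - fib$head_semi_mm[3] && zk < fr$end) {
      zzf <- (zk - fr$fib_cz) / fib$head_semi_mm[3]
      fibm <- matrix(FALSE, nd[1], nd[2])
      if (abs(zzf) <= 1) {
        limf <- 1 - zzf^2
        Xh <- Xf2 / fib$head_semi_mm[1]^2
        Yh <- matrix((y - fr$cy)^2 / fib$head_semi_mm[2]^2, nd[1], nd[2], byrow = TRUE)
        fibm <- Xh + Yh <= limf
      }
      if (zk >= fr$fib_cz)
        fibm <- fibm | (Xf2 + Y2c <= fib$shaft_radius_mm^2)
      sl[fibm & sl == 0L] <- 2L
    }
    lab[, , k] <- sl
  }

  # cement mantle: bone within `cement_thickness_mm` (Euclidean, voxel
  # centre to voxel centre) of the implant -- the same adjacency semantics
  # the segmentation uses, so a noise-free phantom re-segments exactly
  if (has_imp && cem > 0) {
    d2 <- distance_to(lab == 4L, sp, squared = TRUE)
    lab[lab == 1L & d2 <= cem^2] <- 3L
  }

  labels <- label_map(lab, sp)

  hu_lut <- c(-1000, 1000, 1000, 850, 2500, -400)
  hu <- array(hu_lut[lab + 1L], nd)
  if (spec$streak_artifacts || spec$noise_sd_hu > 0) {
    with_seed(spec$seed, {
      if (spec$streak_artifacts && has_imp) {
        phase <- runif(1, 0, 2 * pi)
        theta <- atan2(matrix(y - fr$cy, nd[1], nd[2], byrow = TRUE),
                       matrix(x - fr$cx, nd[1], nd[2]))
        radial <- pmax(0, 1 - sqrt(R2) / (w2 + 10))
        streak2d <- spec$streak_amplitude_hu * cos(8 * theta + phase) * radial
        kz <- which(z >= fr$cut - (if (has_imp) imp$tray_thickness_mm else 0) &
                      z < fr$cut + (if (has_imp) imp$stem_length_mm + cem else 0))
        for (k in kz) hu[, , k] <- hu[, , k] + streak2d
      }
      if (spec$noise_sd_hu > 0)
        hu <- hu + rnorm(length(hu), 0, spec$noise_sd_hu)
    })
  }
  hu <- round(pmin(pmax(hu, -1024), 3071))
  storage.mode(hu) <- "integer"
  ct <- ct_volume(hu, sp)

  # ground-truth landmarks from the constructed geometry
  zidx <- function(mask_by_slice) which(mask_by_slice)[1] - 1L
  imp_slices <- apply(lab == 4L, 3, any)
  bone_slices <- apply(lab == 1L, 3, any)
  tib_fore <- apply(lab == 1L | lab >= 3L, 3, any)
  cut_z <- if (any(imp_slices)) zidx(imp_slices) else zidx(bone_slices)
  distal_end_z <- max(which(tib_fore))  # 0-based exclusive = 1-based last index
  if (has_fib) {
    fl <- fibula_extent_by_slice(lab, sp)
    tip_z <- fl$tip_z; widest_z <- fl$widest_z
  } else {
    tip_z <- widest_z <- NA_integer_
  }
  lm <- tibial_landmarks(
    tibial_cut_z = cut_z,
    fibular_tip_z = tip_z,
    fibular_widest_z = widest_z,
    tubercle_z = cut_z + round(spec$tubercle_below_cut_mm / sp[3]),
    midline_x = fr$cx / sp[1],
    distal_end_z = distal_end_z)

  truth <- list(labels = labels, landmarks = lm)
  if (has_fib) {
    w <- measure_epiphysis_width(labels, cut_z, widest_z)
    part <- partition_zones(lm, w, sp)
    truth$zone_volumes <- compute_volumes(labels, part)
    truth$grade <- grade_defect(labels, lm)
  }
  list(ct = ct, truth = truth)
}

# run code with a private RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  code
}
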