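#' Canonical AORI scenario phantoms
#'
#' A 12-scenario grid of phantoms covering the grade space: for each zone
#' (epiphysis, metaphysis, diaphysis), a medial, a lateral, a bicondylar
#' ("both") and a "deep" pattern. Deep scenarios add a central defect distal
#' to the tibial tubercle plane on top of the zone's bicondylar defect, so
#' they grade III; epiphyseal defects stay proximal to the fibular-tip plane
#' (grade I); metaphyseal defects cross it (IIa one condyle, IIb both);
#' diaphyseal defects lie distal to the tubercle (III).
#'
#' @param base A [phantom_spec()] providing the anatomy; its `defects` are
#'   replaced per scenario.
#' @param noise_sd_hu Noise level applied to every scenario (default 0).
#' @return Tibble with `scenario`, `zone`, `pattern`, `expected_grade`, and
#'   a `spec` list-column of phantom specs.
#' @export
aori_scenarios <- function(base = phantom_spec(), noise_sd_hu = 0) {
  zone_defect <- function(zone, side) {
    semi <- switch(zone,
      epiphysis  = c(6, 4, 2.2),
      metaphysis = c(5, 5, 8),
      diaphysis  = c(4.5, 4, 8))
    defect_spec(zone_target = zone, side = side, semi_axes_mm = semi)
  }
  deep_defect <- function(zone) {
    semi <- switch(zone,
      epiphysis = c(5, 5, 9), metaphysis = c(5.5, 5, 9), diaphysis = c(5, 5, 10))
    defect_spec(zone_target = "diaphysis", side = "central", semi_axes_mm = semi)
  }
  grid <- tidyr::expand_grid(zone = c("epiphysis", "metaphysis", "diaphysis"),
                             pattern = c("medial", "lateral", "both", "deep"))
  specs <- purrr::pmap(grid, function(zone, pattern) {
    defs <- if (pattern == "deep")
      list(zone_defect(zone, "both"), deep_defect(zone))
    else list(zone_defect(zone, pattern))
    sp <- base
    sp$defects <- defs
    sp$noise_sd_hu <- noise_sd_hu
    sp
  })
  expected <- purrr::pmap_int(grid, function(zone, pattern) {
    if (pattern == "deep" || zone == "diaphysis") return(4L)
    if (zone == "epiphysis") return(1L)
    if (pattern == "both") 3L else 2L
  })
  dplyr::mutate(grid,
                scenario = paste(.data$zone, .data$pattern, sep = "_"),
                expected_grade = expected, spec = specs,
                .before = 1)
}
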