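#' Per-zone and total volume accounting
#'
#' Tallies class volumes inside the region of interest (tibial cut to distal
#' end) overall and per fixation zone. The total defect is implant + cement +
#' defect; the total tibial volume is bone + total defect; the remaining-bone
#' ratio is bone / total tibial volume. Fibular bone is excluded from every
#' tibial tally, and the implant volume is only the implant within the ROI.
#' Volumes are exact voxel counts times the voxel volume (no rounding), so
#' zone rows sum to the `total` row to the last voxel.
#'
#' @param labels A [label_map()].
#' @param partition A [zone_partition()][partition_zones].
#' @return A tibble with one row per scope (`total`, `epiphysis`,
#'   `metaphysis`, `diaphysis`) and columns `v_bone`, `v_cement`,
#'   `v_implant`, `v_defect`, `v_total_defect`, `v_total_tibial` (cm^3) and
#'   `remaining_ratio` (`NA` where the scope holds no tibial volume).
#' @export
compute_volumes <- function(labels, partition) {
  stopifnot(inherits(labels, "label_map"), inherits(partition, "zone_partition"))
  v <- voxel_cm3(labels)
  one_scope <- function(scope, rng) {
    cnt <- label_counts(labels, rng)
    v_bone <- cnt[["bone_tibia"]] * v
    v_cement <- cnt[["cement"]] * v
    v_implant <- cnt[["implant"]] * v
    v_defect <- cnt[["defect"]] * v
    v_td <- v_cement + v_implant + v_defect
    v_tt <- v_bone + v_td
    tibble(scope = scope, v_bone = v_bone, v_cement = v_cement,
           v_implant = v_implant, v_defect = v_defect,
           v_total_defect = v_td, v_total_tibial = v_tt,
           remaining_ratio = if (v_tt > 0) v_bone / v_tt else NA_real_)
  }
  zones <- c("epiphysis", "metaphysis", "diaphysis")
  per_zone <- purrr::map2(zones, partition[zones], one_scope)
  roi <- c(partition$epiphysis[1], partition$diaphysis[2])
  out <- dplyr::bind_rows(one_scope("total", roi), per_zone)
  class(out) <- c("volume_report", class(out))
  out
}

#' @export
print.volume_report <- function(x, ...) {
  y <- dplyr::mutate(tibble::as_tibble(x),
                     dplyr::across(dplyr::starts_with("v_"), ~ round(.x, 3)),
                     remaining_ratio = round(.data$remaining_ratio, 4))
  cat("<volume_report> volumes in cm^3\n")
  print(y, ...)
  invisible(x)
}

#' Summarize remaining-bone ratios across a graded cohort
#'
#' Groups per-knee volume reports by AORI grade and zone and returns the
#' mean, standard error and median of the remaining-bone ratio. Undefined
#' ratios (empty scopes) are dropped with a message; groups with a single
#' knee get `NA` SEM.
#'
#' @param reports List of volume reports (one per knee, from
#'   [compute_volumes()]).
#' @param grades Integer AORI grades (1-4), one per report.
#' @return Tibble keyed by `grade`, `scope` with `n`, `mean_ratio`,
#'   `sem_ratio`, `median_ratio`.
#' @export
summarize_cohort <- function(reports, grades) {
  if (length(reports) != length(grades))
    abort("`reports` and `grades` must have equal length.")
  long <- purrr::imap_dfr(reports, function(r, i)
    dplyr::mutate(tibble::as_tibble(r), knee = i, grade = grades[[i]]))
  n_na <- sum(is.na(long$remaining_ratio))
  if (n_na > 0)
    message(sprintf("Dropping %d undefined remaining-bone ratios (empty scopes).", n_na))
  long |>
    dplyr::filter(!is.na(.data$remaining_ratio)) |>
    dplyr::group_by(.data$grade, .data$scope) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_ratio = mean(.data$remaining_ratio),
      sem_ratio = ifelse(dplyr::n() > 1,
                         sd(.data$remaining_ratio) / sqrt(dplyr::n()), NA_real_),
      median_ratio = median(.data$remaining_ratio),
      .groups = "drop")
}
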