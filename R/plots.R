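#' Plot one transverse slice of a volume or label map
#'
#' @param x A [ct_volume()] or [label_map()].
#' @param z0 0-based slice index along the superior-inferior axis.
#' @return A ggplot object (HU greyscale, or discrete tissue colours).
#' @export
plot_slice <- function(x, z0) {
  arr <- unclass(x)
  k <- as.integer(z0) + 1L
  if (k < 1 || k > dim(arr)[3]) abort("Slice index out of range.")
  sp <- spacing_mm(x)
  df <- tidyr::expand_grid(x_mm = (seq_len(dim(arr)[1]) - 1) * sp[1],
                           y_mm = (seq_len(dim(arr)[2]) - 1) * sp[2])
  df <- df[order(df$y_mm, df$x_mm), ]
  df$value <- as.vector(arr[, , k])
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "medial → lateral (mm)", y = "anterior → posterior (mm)",
                  title = sprintf("slice %d", as.integer(z0))) +
    ggplot2::theme_minimal()
  if (inherits(x, "label_map")) {
    cols <- c(background = "black", bone_tibia = "tan", bone_fibula = "tan3",
              cement = "seagreen3", implant = "gold", defect = "red")
    df$tissue <- factor(names(label_codes)[df$value + 1L], names(label_codes))
    p + ggplot2::geom_raster(data = df, ggplot2::aes(fill = .data$tissue)) +
      ggplot2::scale_fill_manual(values = cols, drop = FALSE)
  } else {
    p + ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", name = "HU")
  }
}

#' Stacked per-zone class volumes of a volume report
#' @param object A `volume_report` tibble from [compute_volumes()].
#' @param ... Unused.
#' @method autoplot volume_report
#' @export
autoplot.volume_report <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(.data$scope != "total") |>
    tidyr::pivot_longer(c("v_bone", "v_cement", "v_implant", "v_defect"),
                        names_to = "class", values_to = "cm3") |>
    dplyr::mutate(class = sub("^v_", "", .data$class))
  ggplot2::ggplot(df, ggplot2::aes(.data$scope, .data$cm3, fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = expression(volume ~ (cm^3)), fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot remaining-bone ratio by AORI grade and zone
#'
#' @param cohort_summary Output of [summarize_cohort()].
#' @return A ggplot object.
#' @export
plot_remaining_bone <- function(cohort_summary) {
  df <- dplyr::filter(cohort_summary, .data$scope != "total")
  ggplot2::ggplot(df, ggplot2::aes(factor(aori_label(.data$grade),
                                          levels = aori_label(1:4)),
                                   100 * .data$mean_ratio)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = 100 * (.data$mean_ratio - .data$sem_ratio),
      ymax = 100 * (.data$mean_ratio + .data$sem_ratio)), width = 0.3) +
    ggplot2::facet_wrap(~ .data$scope) +
    ggplot2::labs(x = "AORI grade", y = "remaining bone (%)") +
    ggplot2::theme_minimal()
}
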