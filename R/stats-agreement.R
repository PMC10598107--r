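#' Cross-tabulate two ordinal grade vectors
#'
#' @param grades_a,grades_b Equal-length integer vectors with values in
#'   `levels`.
#' @param levels Ordinal levels (default 1:4, the AORI coding).
#' @param labels Display names for the levels.
#' @return A `contingency_table`: K x K integer matrix (rows = `grades_a`,
#'   columns = `grades_b`).
#' @export
build_table <- function(grades_a, grades_b, levels = 1:4,
                        labels = aori_label(levels)) {
  if (length(grades_a) != length(grades_b) || length(grades_a) == 0L)
    abort("Grade vectors must have equal, positive length.")
  if (!all(grades_a %in% levels) || !all(grades_b %in% levels))
    abort("Out-of-range grade value.")
  tab <- table(factor(grades_a, levels = levels),
               factor(grades_b, levels = levels))
  m <- matrix(as.integer(tab), length(levels), length(levels),
              dimnames = list(labels, labels))
  structure(m, class = c("contingency_table", "matrix", "array"))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Landis-Koch interpretation of a kappa value
#'
#' Bands with the upper edge inclusive: (0, 0.20\] slight, (0.20, 0.40\]
#' fair, (0.40, 0.60\] moderate, (0.60, 0.80\] substantial, (0.80, 1\]
#' almost perfect; kappa of 0 or less indicates poor agreement.
#'
#' @param kappa Numeric in \[-1, 1\].
#' @return Character band name.
#' @export
landis_koch <- function(kappa) {
  stopifnot(all(is.finite(kappa)), all(kappa >= -1 & kappa <= 1))
  bands <- c("poor", "slight", "fair", "moderate", "substantial", "almost perfect")
  bands[findInterval(kappa, c(0, 0.2, 0.4, 0.6, 0.8), left.open = TRUE) + 1L]
}

#' Cohen's kappa for a square contingency table
#'
#' Unweighted chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e)
#' with p_o the diagonal proportion and p_e the product-margin expectation.
#' An optional linear- or quadratic-weighted variant is available, but the
#' default (and the convention the Landis-Koch interpretation assumes here)
#' is unweighted. The p-value is a large-sample normal approximation of the
#' test of kappa = 0.
#'
#' @param tab A square matrix or `contingency_table` of counts.
#' @param weighting `"none"` (default), `"linear"` or `"quadratic"`.
#' @return An `agreement_result` with `kappa`, `observed_agreement`,
#'   `expected_agreement`, `interpretation`, `se0`, `statistic`, `p_value`,
#'   `n`.
#' @export
cohens_kappa <- function(tab, weighting = c("none", "linear", "quadratic")) {
  weighting <- match.arg(weighting)
  m <- unclass(as.matrix(tab))
  if (nrow(m) != ncol(m)) abort("Contingency table must be square.")
  if (any(m < 0) || sum(m) == 0) abort("Counts must be non-negative with a positive total.")
  k <- nrow(m)
  n <- sum(m)
  p <- m / n
  r <- rowSums(p); cc <- colSums(p)
  w <- switch(weighting,
    none = diag(k),
    linear = 1 - abs(outer(seq_len(k), seq_len(k), "-")) / (k - 1),
    quadratic = 1 - (outer(seq_len(k), seq_len(k), "-") / (k - 1))^2)
  p_o <- sum(w * p)
  p_e <- sum(w * outer(r, cc))
  if (1 - p_e < .Machine$double.eps^0.5) {
    warn("Degenerate table (expected agreement 1): kappa undefined.")
    res <- list(kappa = NA_real_, observed_agreement = p_o,
                expected_agreement = p_e, interpretation = NA_character_,
                se0 = NA_real_, statistic = NA_real_, p_value = NA_real_,
                n = n, weighting = weighting, table = m)
    return(structure(res, class = "agreement_result"))
  }
  kappa <- (p_o - p_e) / (1 - p_e)
  # large-sample SE of kappa under the null (Fleiss, Cohen & Everitt form,
  # unweighted); for weighted kappa the same form with weighted margins is a
  # serviceable approximation
  wr <- as.numeric(w %*% cc)
  wc <- as.numeric(t(w) %*% r)
  num <- sum(outer(r, cc) * (w - outer(wr, wc, "+"))^2) - p_e^2
  se0 <- sqrt(max(num, 0) / (n * (1 - p_e)^2))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  res <- list(kappa = kappa, observed_agreement = p_o, expected_agreement = p_e,
              interpretation = landis_koch(kappa), se0 = se0, statistic = z,
              p_value = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
              n = n, weighting = weighting, table = m)
  structure(res, class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa (%s): %.3f  [%s]\n", x$weighting, x$kappa,
              x$interpretation))
  cat(sprintf("  observed %.3f, expected %.3f, n = %d, z = %.2f, p = %.3g\n",
              x$observed_agreement, x$expected_agreement, x$n, x$statistic,
              x$p_value))
  invisible(x)
}

#' @rdname cohens_kappa
#' @param x An `agreement_result`.
#' @param ... Unused.
#' @method tidy agreement_result
#' @export
tidy.agreement_result <- function(x, ...) {
  tibble(estimate = x$kappa, statistic = x$statistic, p.value = x$p_value,
         std.error = x$se0, interpretation = x$interpretation)
}

#' @rdname cohens_kappa
#' @method glance agreement_result
#' @export
glance.agreement_result <- function(x, ...) {
  tibble(kappa = x$kappa, observed_agreement = x$observed_agreement,
         expected_agreement = x$expected_agreement, n = x$n,
         interpretation = x$interpretation, p.value = x$p_value)
}

#' @param object A `contingency_table`.
#' @param ... Unused.
#' @method autoplot contingency_table
#' @export
autoplot.contingency_table <- function(object, ...) {
  df <- tibble::as_tibble(as.data.frame(as.table(unclass(object))))
  names(df) <- c("a", "b", "n")
  ggplot2::ggplot(df, ggplot2::aes(.data$b, .data$a, fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = "comparator grade", y = "reference grade", fill = "knees") +
    ggplot2::theme_minimal()
}
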