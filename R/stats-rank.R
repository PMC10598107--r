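#' Spearman rank correlation with midranks for ties
#'
#' The product-moment correlation of the midrank vectors, the convention
#' under which the agreement of ordinal grade vectors is reported. The
#' two-sided p-value uses the t approximation with n - 2 degrees of freedom.
#'
#' @param grades_a,grades_b Equal-length numeric vectors (length >= 3).
#' @return A `spearman_cor` list: `rho`, `n`, `statistic` (t), `df`,
#'   `p_value`.
#' @export
spearman_tied <- function(grades_a, grades_b) {
  if (length(grades_a) != length(grades_b))
    abort("Vectors must have equal length.")
  n <- length(grades_a)
  if (n < 3) abort("Need at least 3 pairs.")
  ra <- rank(grades_a); rb <- rank(grades_b)
  if (sd(ra) == 0 || sd(rb) == 0) {
    warn("Zero rank variance: correlation undefined.")
    return(structure(list(rho = NA_real_, n = n, statistic = NA_real_,
                          df = n - 2L, p_value = NA_real_),
                     class = "spearman_cor"))
  }
  rho <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  structure(list(rho = rho, n = n, statistic = tstat, df = n - 2L,
                 p_value = 2 * pt(-abs(tstat), n - 2)),
            class = "spearman_cor")
}

#' @export
print.spearman_cor <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (n = %d, t = %.2f, p = %.3g)\n",
              x$rho, x$n, x$statistic, x$p_value))
  invisible(x)
}

#' @rdname spearman_tied
#' @param x A `spearman_cor`.
#' @param ... Unused.
#' @method tidy spearman_cor
#' @export
tidy.spearman_cor <- function(x, ...) {
  tibble(estimate = x$rho, statistic = x$statistic, p.value = x$p_value,
         df = x$df, n = x$n)
}

#' Median and quartiles of an ordinal grade vector
#'
#' Nearest-rank quantiles (the order statistic closest to n*p, R type 3),
#' which always return observed grade values and match the convention under
#' which ordinal grade medians and IQRs are reported.
#'
#' @param grades Non-empty numeric/ordinal vector.
#' @return Named numeric: `median`, `q1`, `q3`.
#' @export
ordinal_median_iqr <- function(grades) {
  if (length(grades) == 0L) abort("Empty grade vector.")
  q <- quantile(grades, c(0.5, 0.25, 0.75), type = 3, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Friedman test for matched ordinal columns
#'
#' Within-row midranks with tie correction; the statistic is
#' `(k-1) * (sum_j R_j^2 - n^2 k (k+1)^2 / 4) / (A - C)` where `A` is the
#' sum of squared ranks and `C = n k (k+1)^2 / 4` (the tie-free case reduces
#' to the classical chi-square form). All-constant rows give statistic 0 and
#' p = 1. Post-hoc: pairwise Wilcoxon signed-rank tests (normal
#' approximation) with Bonferroni adjustment.
#'
#' @param matched n x k matrix (rows = subjects, columns = related methods).
#' @param posthoc Run pairwise comparisons (default TRUE for k > 2).
#' @return A `friedman_result`: `statistic`, `df`, `p_value`, `n`, `k`,
#'   and a `posthoc` tibble (`pair`, `p_value`, `p_adjusted`).
#' @export
friedman_ordinal <- function(matched, posthoc = TRUE) {
  m <- as.matrix(matched)
  if (nrow(m) < 2 || ncol(m) < 2) abort("Need >= 2 rows and >= 2 columns.")
  if (any(is.na(m))) abort("Missing cells are not allowed.")
  n <- nrow(m); k <- ncol(m)
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  if (A - C < .Machine$double.eps) {
    stat <- 0; p <- 1
  } else {
    stat <- (k - 1) * (sum(Rj^2) - n^2 * k * (k + 1)^2 / 4) / (A - C)
    p <- pchisq(stat, k - 1, lower.tail = FALSE)
  }
  ph <- NULL
  if (posthoc && k > 2) {
    pairs <- utils::combn(k, 2)
    pv <- apply(pairs, 2, function(ij) {
      d <- m[, ij[1]] - m[, ij[2]]
      if (all(d == 0)) return(1)
      stats::wilcox.test(m[, ij[1]], m[, ij[2]], paired = TRUE,
                         exact = FALSE, correct = TRUE)$p.value
    })
    nm <- apply(pairs, 2, function(ij) {
      cn <- colnames(m) %||% paste0("col", seq_len(k))
      paste(cn[ij[1]], cn[ij[2]], sep = " vs ")
    })
    ph <- tibble(pair = nm, p_value = pv,
                 p_adjusted = pmin(pv * ncol(pairs), 1))
  }
  structure(list(statistic = stat, df = k - 1L,
                 p_value = p, n = n, k = k, posthoc = ph),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman chi-squared = %.3f, df = %d, p = %.3g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  if (!is.null(x$posthoc)) {
    cat("Post-hoc (Wilcoxon signed-rank, Bonferroni):\n")
    print(x$posthoc)
  }
  invisible(x)
}

#' Kruskal-Wallis test with Dunn post-hoc comparisons
#'
#' Tie-corrected H statistic with a chi-square p-value; pairwise Dunn z
#' tests on the pooled midranks with Bonferroni adjustment.
#'
#' @param groups List of >= 2 non-empty numeric vectors.
#' @param posthoc Run Dunn comparisons (default TRUE).
#' @return A `kruskal_result`: `statistic` (H), `df`, `p_value`, `n`, and a
#'   `posthoc` tibble (`pair`, `z`, `p_value`, `p_adjusted`).
#' @export
kruskal_dunn <- function(groups, posthoc = TRUE) {
  if (!is.list(groups) || length(groups) < 2)
    abort("Need a list of at least 2 groups.")
  if (any(lengths(groups) == 0)) abort("Empty group.")
  g <- rep(seq_along(groups), lengths(groups))
  x <- unlist(groups, use.names = FALSE)
  N <- length(x)
  r <- rank(x)
  Rbar <- tapply(r, g, mean)
  nj <- lengths(groups)
  H0 <- 12 / (N * (N + 1)) * sum(nj * (Rbar - (N + 1) / 2)^2)
  ties <- table(x)
  tie_corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  if (tie_corr <= 0) {
    stat <- 0; p <- 1  # all observations identical
  } else {
    stat <- H0 / tie_corr
    p <- pchisq(stat, length(groups) - 1, lower.tail = FALSE)
  }
  ph <- NULL
  if (posthoc && length(groups) > 1) {
    sig2 <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1)))
    pairs <- utils::combn(length(groups), 2)
    zs <- apply(pairs, 2, function(ij) {
      (Rbar[ij[1]] - Rbar[ij[2]]) /
        sqrt(sig2 * (1 / nj[ij[1]] + 1 / nj[ij[2]]))
    })
    pv <- 2 * pnorm(-abs(zs))
    nm <- apply(pairs, 2, function(ij) {
      gn <- names(groups) %||% paste0("group", seq_along(groups))
      paste(gn[ij[1]], gn[ij[2]], sep = " vs ")
    })
    ph <- tibble(pair = nm, z = as.numeric(zs), p_value = pv,
                 p_adjusted = pmin(pv * ncol(pairs), 1))
  }
  structure(list(statistic = stat, df = length(groups) - 1L, p_value = p,
                 n = N, posthoc = ph),
            class = "kruskal_result")
}

#' @export
print.kruskal_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis H = %.3f, df = %d, p = %.3g (n = %d)\n",
              x$statistic, x$df, x$p_value, x$n))
  if (!is.null(x$posthoc)) {
    cat("Post-hoc (Dunn, Bonferroni):\n")
    print(x$posthoc)
  }
  invisible(x)
}
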