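#' Published agreement tables between grading methods
#'
#' The packaged 4 x 4 contingency tables of intraoperative AORI grade (rows)
#' against the preoperative 3D-CT grade and against the preoperative X-ray
#' grade (columns), for the 99-knee revision cohort the pipeline's agreement
#' statistics are benchmarked on. Plain-text copies live in
#' `inst/extdata/`.
#'
#' @param method `"ct"` or `"xray"`.
#' @return A `contingency_table` (rows = intraoperative, columns =
#'   preoperative grade).
#' @export
aori_agreement_table <- function(method = c("ct", "xray")) {
  method <- match.arg(method)
  counts <- switch(method,
    ct = c(21, 0, 0, 0,
           1, 23, 3, 2,
           6, 7, 17, 5,
           0, 1, 0, 13),
    xray = c(20, 1, 0, 0,
             14, 10, 3, 2,
             15, 11, 5, 4,
             1, 2, 0, 11))
  m <- matrix(as.integer(counts), 4, 4, byrow = TRUE,
              dimnames = list(aori_label(1:4), aori_label(1:4)))
  structure(m, class = c("contingency_table", "matrix", "array"))
}

#' Reconstruct per-knee grade pairs from an agreement table
#'
#' Expands the packaged counts into one row per knee, in deterministic
#' (row-major) order.
#'
#' @param method `"ct"` or `"xray"`.
#' @return Tibble with `knee_id`, `intraop`, `preop` (grades 1-4).
#' @export
aori_agreement_pairs <- function(method = c("ct", "xray")) {
  m <- aori_agreement_table(method)
  idx <- which(unclass(m) > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  n <- unclass(m)[idx]
  tibble(knee_id = seq_len(sum(n)),
         intraop = rep(idx[, 1], n),
         preop = rep(idx[, 2], n))
}

#' Specify a grading-cohort simulation
#'
#' Each knee draws an intraoperative grade from `intraop_distribution`, then
#' CT and X-ray grades independently from the corresponding rows of the
#' confusion matrices (probability of each preoperative grade given the
#' intraoperative grade). Defaults are the row-normalized packaged agreement
#' tables, so simulated cohorts converge to the published agreement
#' structure as n grows.
#'
#' @param n_knees Number of knees.
#' @param intraop_distribution Probability over the 4 grades (default: the
#'   cohort margins 21/29/35/14 over 99).
#' @param ct_confusion,xray_confusion 4 x 4 row-stochastic matrices.
#' @param seed Integer seed.
#' @return A validated `cohort_spec`.
#' @export
cohort_spec <- function(n_knees,
                        intraop_distribution = NULL,
                        ct_confusion = NULL,
                        xray_confusion = NULL,
                        seed = 1L) {
  if (n_knees < 1) abort("`n_knees` must be positive.")
  ctm <- unclass(aori_agreement_table("ct"))
  xrm <- unclass(aori_agreement_table("xray"))
  intraop_distribution <- intraop_distribution %||% (rowSums(ctm) / sum(ctm))
  ct_confusion <- ct_confusion %||% (ctm / rowSums(ctm))
  xray_confusion <- xray_confusion %||% (xrm / rowSums(xrm))
  if (abs(sum(intraop_distribution) - 1) > 1e-12)
    abort("`intraop_distribution` must sum to 1.")
  for (m in list(ct = ct_confusion, xray = xray_confusion)) {
    if (!all(dim(m) == c(4, 4)) || any(m < 0) ||
        any(abs(rowSums(m) - 1) > 1e-12))
      abort("Confusion matrices must be 4 x 4 row-stochastic.")
  }
  structure(list(n_knees = as.integer(n_knees),
                 intraop_distribution = as.numeric(intraop_distribution),
                 ct_confusion = ct_confusion, xray_confusion = xray_confusion,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a grading cohort
#'
#' @param spec A [cohort_spec()].
#' @return Tibble with `knee_id`, `intraop`, `ct`, `xray` (grades 1-4),
#'   reproducible given the spec's seed.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_knees
  with_seed(spec$seed, {
    intraop <- sample.int(4L, n, replace = TRUE, prob = spec$intraop_distribution)
    draw_given <- function(conf) {
      out <- integer(n)
      for (g in 1:4) {
        i <- which(intraop == g)
        if (length(i) > 0)
          out[i] <- sample.int(4L, length(i), replace = TRUE, prob = conf[g, ])
      }
      out
    }
    tibble(knee_id = seq_len(n), intraop = intraop,
           ct = draw_given(spec$ct_confusion),
           xray = draw_given(spec$xray_confusion))
  })
}

#' Recompute the published agreement statistics from the packaged tables
#'
#' Runs the full ordinal agreement battery on the per-knee grade pairs
#' reconstructed from the packaged contingency tables: Cohen's kappa with
#' Landis-Koch interpretation, tie-corrected Spearman correlation, the
#' correctly-predicted fraction of intraoperative IIb defects, and the
#' per-method median/IQR.
#'
#' @return List with `kappa` (tibble, one row per method), `spearman`
#'   (tibble), `iib_correct` (tibble), `median_iqr` (tibble).
#' @export
reproduce_agreement_stats <- function() {
  methods <- c("ct", "xray")
  pairs <- purrr::map(methods, aori_agreement_pairs)
  names(pairs) <- methods
  kap <- purrr::imap_dfr(pairs, function(p, m) {
    k <- cohens_kappa(build_table(p$intraop, p$preop))
    dplyr::mutate(glance(k), method = m, .before = 1)
  })
  sp <- purrr::imap_dfr(pairs, function(p, m) {
    s <- spearman_tied(p$intraop, p$preop)
    dplyr::mutate(tidy(s), method = m, .before = 1)
  })
  iib <- purrr::imap_dfr(pairs, function(p, m) {
    n_iib <- sum(p$intraop == 3)
    tibble(method = m, n_intraop_iib = n_iib,
           n_correct = sum(p$intraop == 3 & p$preop == 3),
           pct_correct = 100 * sum(p$intraop == 3 & p$preop == 3) / n_iib)
  })
  med <- dplyr::bind_rows(
    tibble(method = "intraop", !!!ordinal_median_iqr(pairs$ct$intraop)),
    tibble(method = "ct", !!!ordinal_median_iqr(pairs$ct$preop)),
    tibble(method = "xray", !!!ordinal_median_iqr(pairs$xray$preop)))
  list(kappa = kap, spearman = sp, iib_correct = iib, median_iqr = med)
}
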