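# Brute-force oracles coded independently of the implementation.

kappa_oracle <- function(m) {
  n <- sum(m); agree <- 0; chance <- 0
  for (i in seq_len(nrow(m))) {
    agree <- agree + m[i, i] / n
    chance <- chance + (sum(m[i, ]) / n) * (sum(m[, i]) / n)
  }
  (agree - chance) / (1 - chance)
}

spearman_oracle <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  ma <- ra - mean(ra); mb <- rb - mean(rb)
  sum(ma * mb) / sqrt(sum(ma^2) * sum(mb^2))
}

test_that("the packaged agreement tables have the published margins", {
  ct <- aori_agreement_table("ct"); xr <- aori_agreement_table("xray")
  expect_identical(rowSums(unclass(ct)), rowSums(unclass(xr)))
  expect_equal(unname(rowSums(unclass(ct))), c(21, 29, 35, 14))
  expect_equal(unname(colSums(unclass(ct))), c(28, 31, 20, 20))
  expect_equal(unname(colSums(unclass(xr))), c(50, 24, 8, 17))
  p <- aori_agreement_pairs("ct")
  expect_identical(nrow(p), 99L)
  expect_identical(unclass(build_table(p$intraop, p$preop)),
                   unclass(ct), ignore_attr = TRUE)
})

test_that("kappa agrees with a brute-force oracle on random tables", {
  set.seed(21)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    m <- matrix(rpois(k * k, 3) + diag(k) * rpois(k, 5), k, k)
    if (sum(m) == 0) m[1, 1] <- 1
    res <- cohens_kappa(m)
    expect_equal(res$kappa, kappa_oracle(m), tolerance = 1e-12)
    # symmetry under transposition and simultaneous permutation
    expect_equal(cohens_kappa(t(m))$kappa, res$kappa, tolerance = 1e-12)
    pp <- sample(k)
    expect_equal(cohens_kappa(m[pp, pp])$kappa, res$kappa, tolerance = 1e-12)
  }
  expect_equal(cohens_kappa(diag(5) * 3)$kappa, 1)
})

test_that("degenerate single-category tables flag kappa as undefined", {
  m <- matrix(0, 3, 3); m[1, 1] <- 10
  expect_warning(res <- cohens_kappa(m), "undefined")
  expect_true(is.na(res$kappa))
})

test_that("Landis-Koch banding is exact at the band edges", {
  edges <- c(-0.2, 0, 0.01, 0.20, 0.21, 0.40, 0.41, 0.60, 0.61, 0.80, 0.81, 1)
  want <- c("poor", "poor", "slight", "slight", "fair", "fair", "moderate",
            "moderate", "substantial", "substantial", "almost perfect",
            "almost perfect")
  expect_identical(landis_koch(edges), want)
})

test_that("tied Spearman equals the midrank Pearson oracle and cor.test", {
  set.seed(31)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(1:4, n, replace = TRUE)
    if (length(unique(a)) < 2 || length(unique(b)) < 2) next
    res <- spearman_tied(a, b)
    expect_equal(res$rho, spearman_oracle(a, b), tolerance = 1e-12)
    expect_equal(res$rho, unname(cor(a, b, method = "spearman")),
                 tolerance = 1e-12)
  }
  # strictly monotone pairing without ties
  expect_equal(spearman_tied(1:7, (1:7)^3)$rho, 1)
  expect_warning(res0 <- spearman_tied(c(2, 2, 2), c(1, 2, 3)), "undefined")
  expect_true(is.na(res0$rho))
})

test_that("ordinal median/IQR uses the nearest-rank convention", {
  xr <- rep(1:4, c(50, 24, 8, 17))
  io <- rep(1:4, c(21, 29, 35, 14))
  ct <- rep(1:4, c(28, 31, 20, 20))
  expect_equal(ordinal_median_iqr(xr), c(median = 1, q1 = 1, q3 = 2))
  expect_equal(ordinal_median_iqr(io), c(median = 2, q1 = 2, q3 = 3))
  expect_equal(ordinal_median_iqr(ct), c(median = 2, q1 = 1, q3 = 3))
})

test_that("Friedman statistic matches the closed form and stats::friedman.test", {
  # perfectly ordered columns: chi-square = 2n for k = 3
  m <- cbind(rep(1, 10), rep(2, 10), rep(3, 10))
  res <- friedman_ordinal(m)
  expect_equal(res$statistic, 20)
  # identical columns
  expect_equal(friedman_ordinal(cbind(1:5, 1:5, 1:5))$statistic, 0)
  expect_equal(friedman_ordinal(cbind(1:5, 1:5, 1:5))$p_value, 1)
  # tie-free random data against the independent implementation
  set.seed(41)
  for (i in 1:10) {
    mm <- t(replicate(6, sample(seq_len(4))))
    want <- unname(stats::friedman.test(mm)$statistic)
    expect_equal(friedman_ordinal(mm)$statistic, want, tolerance = 1e-12)
  }
  # with ties: compare to an independently coded variance-ratio form
  for (i in 1:10) {
    mm <- matrix(sample(1:3, 24, replace = TRUE), 8, 3)
    r <- t(apply(mm, 1, rank))
    sst <- sum((colMeans(r) - mean(r))^2) * nrow(mm) * (ncol(mm) - 1)
    sse <- sum((r - mean(r))^2) / nrow(mm)
    want <- if (sse == 0) 0 else nrow(mm) * (ncol(mm) - 1) *
      sum((colMeans(r) - mean(r))^2) / (sum((r - mean(r))^2) / nrow(mm))
    expect_equal(friedman_ordinal(mm)$statistic, want, tolerance = 1e-10)
  }
})

test_that("simulated cohorts show X-ray undergrading in the Friedman battery", {
  coh <- simulate_cohort(cohort_spec(3000, seed = 17L))
  res <- friedman_ordinal(as.matrix(coh[, c("intraop", "ct", "xray")]))
  expect_lt(res$p_value, 0.001)
  expect_lt(mean(coh$xray), mean(coh$intraop))   # less severe grading
  expect_identical(nrow(res$posthoc), 3L)
  expect_true(all(res$posthoc$p_adjusted >= res$posthoc$p_value))
})

test_that("Kruskal-Wallis matches the hand computation and kruskal.test", {
  res <- kruskal_dunn(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(res$statistic, 27 / 7, tolerance = 1e-12)   # ranks 1..6, no ties
  set.seed(51)
  for (i in 1:10) {
    g <- list(sample(1:5, 7, TRUE), sample(1:5, 5, TRUE), sample(1:5, 6, TRUE))
    want <- unname(stats::kruskal.test(g)$statistic)
    expect_equal(kruskal_dunn(g)$statistic, want, tolerance = 1e-12)
  }
  expect_equal(kruskal_dunn(list(c(2, 2), c(2, 2)))$statistic, 0)
  expect_error(kruskal_dunn(list(1:3)), "2 groups")
})

test_that("sensitivity and power are mutual inverses and monotone", {
  for (n in c(10, 50, 99, 200)) for (pw in c(0.5, 0.8, 0.9)) {
    rho <- spearman_sensitivity(n, 0.05, pw)
    expect_equal(spearman_power(n, rho, 0.05), pw, tolerance = 1e-10)
  }
  expect_equal(spearman_power(99, 0, 0.05), 0.025, tolerance = 1e-12)
  # strictly increasing in n and rho
  expect_true(spearman_power(150, 0.2) > spearman_power(50, 0.2))
  expect_true(spearman_power(99, 0.3) > spearman_power(99, 0.2))
  expect_error(spearman_sensitivity(3), "at least 4")
})
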