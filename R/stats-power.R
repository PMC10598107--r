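#' Power of a two-sided Spearman correlation test
#'
#' Fisher z approximation: `power = Phi(atanh(rho) * sqrt(n - 3) -
#' z_{1 - alpha/2})`. At `rho = 0` this returns the one-tailed rejection mass
#' `alpha / 2`.
#'
#' @param n Sample size (>= 4).
#' @param rho True correlation (-1 < rho < 1).
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
spearman_power <- function(n, rho, alpha = 0.05) {
  if (n < 4) abort("`n` must be at least 4.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (abs(rho) >= 1) abort("`rho` must be inside (-1, 1).")
  pnorm(atanh(abs(rho)) * sqrt(n - 3) - qnorm(1 - alpha / 2))
}

#' Minimal detectable Spearman correlation (sensitivity)
#'
#' The effect size a two-sided test at level `alpha` detects with the given
#' power at sample size `n`, via the Fisher z approximation:
#' `tanh((z_{1 - alpha/2} + z_{power}) / sqrt(n - 3))`. Inverse of
#' [spearman_power()] in `rho`.
#'
#' @param n Sample size (>= 4).
#' @param alpha Two-sided significance level.
#' @param power Target power in (0, 1).
#' @return Minimal detectable correlation.
#' @export
spearman_sensitivity <- function(n, alpha = 0.05, power = 0.80) {
  if (n < 4) abort("`n` must be at least 4.")
  if (alpha <= 0 || alpha >= 1) abort("`alpha` must be in (0, 1).")
  if (power <= 0 || power >= 1) abort("`power` must be in (0, 1).")
  tanh((qnorm(1 - alpha / 2) + qnorm(power)) / sqrt(n - 3))
}

#' Monte-Carlo power of the Spearman test
#'
#' Simulates bivariate-normal samples at a given correlation and counts
#' rejections of the two-sided Spearman test (t approximation), as an
#' empirical check on the analytic [spearman_power()]. Note the Fisher z
#' analytic value describes the test of the latent Pearson correlation; on
#' bivariate-normal data the Spearman rho is attenuated slightly
#' (rho_s = 6/pi * asin(rho/2)), so the simulation is run at the latent
#' correlation whose Spearman value equals `rho`.
#'
#' @param n Sample size per replicate.
#' @param rho Target Spearman correlation.
#' @param alpha Two-sided level.
#' @param n_sim Number of replicates.
#' @param seed Integer seed.
#' @return Empirical power (rejection proportion).
#' @export
spearman_power_mc <- function(n, rho, alpha = 0.05, n_sim = 10000, seed = 1L) {
  if (n < 4) abort("`n` must be at least 4.")
  rho_latent <- 2 * sin(rho * pi / 6)  # invert rho_s = 6/pi asin(r/2)
  with_seed(seed, {
    rej <- logical(n_sim)
    for (i in seq_len(n_sim)) {
      x <- rnorm(n)
      y <- rho_latent * x + sqrt(1 - rho_latent^2) * rnorm(n)
      rej[i] <- spearman_tied(x, y)$p_value < alpha
    }
    mean(rej)
  })
}
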