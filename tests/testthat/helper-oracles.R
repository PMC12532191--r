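# Independent brute-force oracles and shared fixtures for the test suite.
# These deliberately re-derive quantities with the most literal possible
# code paths (explicit loops, closed forms) so they stay independent of the
# package implementation they check.

# direct evaluation of the normalized autocorrelation estimator at bin lags
acf_direct <- function(x, lags_bins) {
  n <- length(x)
  out <- numeric(length(lags_bins))
  for (j in seq_along(lags_bins)) {
    k <- lags_bins[j]
    num <- 0
    for (t in 1:(n - k)) num <- num + x[t] * x[t + k]
    num <- num / (n - k)
    out[j] <- num / (mean(x[1:(n - k)]) * mean(x[(k + 1):n]))
  }
  out
}

# brute-force unordered pair counts per distance bin (double loop)
pair_count_direct <- function(x, y, bin_width, n_bins) {
  h <- numeric(n_bins)
  n <- length(x)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
      k <- floor(d / bin_width) + 1
      if (k <= n_bins) h[k] <- h[k] + 1
    }
  }
  h
}

# analytic localization pair correlation of the clustered blinking process:
# Thomas process (cluster intensity kappa /nm^2, Poisson(mu) members,
# Gaussian spread sigma) plus CSR background lam_bg, each molecule blinking
# into 1 + Geometric(mean alpha - 1) localizations jittered by `prec`.
analytic_pc_curve <- function(r, kappa, mu, sigma, lam_bg, alpha, prec) {
  lam_m <- kappa * mu + lam_bg
  lam_loc <- alpha * lam_m
  blink2 <- 2 * alpha * (alpha - 1)  # E[k(k-1)] for k = 1 + Geom
  s2 <- sigma^2 + prec^2
  1 +
    lam_m * blink2 / lam_loc^2 / (4 * pi * prec^2) * exp(-r^2 / (4 * prec^2)) +
    kappa * mu^2 * alpha^2 / lam_loc^2 / (4 * pi * s2) * exp(-r^2 / (4 * s2))
}

# population (pseudo-true) cluster radius: the package model fitted to the
# analytic curve with the matched weight profile
population_xi <- function(kappa, mu, sigma, lam_bg, alpha, prec,
                          bin_width = 10, r_max = 500, roi_side = 3000,
                          n_ref = 2000) {
  r_lo <- seq(0, r_max - bin_width, by = bin_width)
  r_hi <- r_lo + bin_width
  r <- (r_lo + r_hi) / 2
  g <- analytic_pc_curve(r, kappa, mu, sigma, lam_bg, alpha, prec)
  w <- memquant:::csr_pair_expectation(n_ref, roi_side, r_lo, r_hi)
  fit_pc_model(r, g, w, psf_sigma = prec)$xi
}

# scaled-down qSMLM ground-truth parameters used by fast pipeline tests
scaled_smlm_pars <- function(...) {
  utils::modifyList(list(
    field_size = 4, n_frames = 5000, cluster_density = 5,
    molecules_per_cluster_mean = 10, cluster_sigma = 30,
    background_density = 20, alpha_true = 3.3, dark_time_scale = 2.5,
    localization_precision = 15, n_fiducials = 3
  ), list(...))
}
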