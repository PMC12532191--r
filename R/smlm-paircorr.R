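#' Pair-correlation analysis of localizations in a square ROI
#'
#' Computes the empirical pair-correlation function g(r) on distance bins of
#' width `bin_width` up to `r_max`: observed unordered pair counts divided by
#' the expectation under complete spatial randomness, edge-corrected with the
#' exact isotropic set covariance of the square window,
#' `gamma(r) = L^2 - 4 L r / pi + r^2 / pi` for distances within `L`. The model
#' `g(r) = c0 + A_psf exp(-r^2 / (4 sigma^2)) + A_c exp(-r / xi)` is then
#' fitted by weighted least squares: the baseline `c0` (near 1) absorbs
#' realization-level long-range density inhomogeneity of the ROI (a finite
#' number of nanodomains per ROI leaves a correlated offset at large r
#' that would otherwise bias the exponential term); the Gaussian term absorbs the
#' blinking/localization-noise correlation at the PSF-precision scale
#' (pair distances between repeated localizations of one molecule are
#' Gaussian with per-axis SD `sqrt(2) * precision`), while the exponential
#' term carries the nanodomain correlation length `xi` (the reported
#' cluster radius).
#'
#' @param table drift-corrected localization table (fiducials excluded).
#' @param roi an [roi()] object; only points inside are used.
#' @param bin_width distance bin width in nm.
#' @param r_max maximum distance in nm.
#' @param psf_sigma expected PSF-term width in nm, used to bound the
#'   Gaussian term to `[0.7, 1.3] * psf_sigma` and break the degeneracy with
#'   the exponential cluster term; defaults to the mean of the table's
#'   `precision_nm` column, or unconstrained when unavailable.
#' @param fit_r_max largest distance (nm) entering the model fit; the g(r)
#'   curve is still estimated out to `r_max`. Restricting the fit to the
#'   structured range keeps realization-level long-range noise from
#'   leveraging the exponential term.
#' @return object of class `pair_correlation`: list with `r_nm` (bin
#'   centers), `g`, `expected_pairs`, `n_points`, `density` (points/um^2),
#'   `converged`, and when the fit converged `cluster_radius` (xi, nm),
#'   `fitted_psf_sigma` (nm), `cluster_amplitude`, `psf_amplitude`.
#' @export
pair_correlation <- function(table, roi, bin_width = 10, r_max = 500,
                             psf_sigma = NULL, fit_r_max = 250) {
  stopifnot(inherits(roi, "roi"))
  check_scalar(bin_width, "bin_width", 0, strict_lower = TRUE)
  check_scalar(r_max, "r_max", bin_width)
  if (!is.null(table$is_fiducial)) table <- table[!table$is_fiducial, ]
  if (is.null(psf_sigma) && !is.null(table$precision_nm)) {
    ps <- mean(table$precision_nm, na.rm = TRUE)
    if (is.finite(ps) && ps > 0) psf_sigma <- ps
  }
  sub <- roi_subset(table, roi)
  n <- nrow(sub)
  n_bins <- floor(r_max / bin_width)
  r_lo <- (seq_len(n_bins) - 1) * bin_width
  r_hi <- r_lo + bin_width
  r_mid <- (r_lo + r_hi) / 2

  counts <- pair_distance_hist(sub$x_nm, sub$y_nm, bin_width, n_bins)
  expected <- csr_pair_expectation(n, roi$side, r_lo, r_hi)
  g <- ifelse(expected > 0, counts / expected, NA_real_)

  out <- list(r_nm = r_mid, g = g, counts = counts,
              expected_pairs = expected, n_points = n,
              density = n / roi$area_um2, bin_width = bin_width,
              r_max = r_max, converged = FALSE)
  class(out) <- "pair_correlation"
  if (n < 20 || all(!is.finite(g))) return(out)

  fit <- try(fit_pc_model(r_mid, g, expected, psf_sigma = psf_sigma,
                          fit_r_max = fit_r_max), silent = TRUE)
  if (!inherits(fit, "try-error") && fit$converged) {
    out$converged <- TRUE
    out$cluster_radius <- fit$xi
    out$fitted_psf_sigma <- fit$sigma
    out$cluster_amplitude <- fit$A_c
    out$psf_amplitude <- fit$A_psf
    out$fit <- fit
  }
  out
}

# Expected unordered CSR pair count per distance bin in a square window of
# side L: C(n,2) * integral_bin 2 pi r gamma(r) dr / L^4, with gamma the
# isotropic set covariance of the square (exact for r <= L).
csr_pair_expectation <- function(n, L, r_lo, r_hi) {
  stopifnot(all(r_hi <= L))
  primitive <- function(r) pi * L^2 * r^2 - (8 / 3) * L * r^3 + r^4 / 2
  choose(n, 2) * (primitive(r_hi) - primitive(r_lo)) / L^4
}

#' Fit the pair-correlation model to a g(r) curve
#'
#' Weighted least squares of
#' `g(r) = c0 + A_psf exp(-r^2/(4 sigma^2)) + A_c exp(-r/xi)` with weights
#' equal to the expected CSR pair counts per bin (inverse variance of g
#' under Poisson pair statistics), multi-started over `xi`. Exposed so that
#' population (pseudo-true) parameter values can be computed by fitting the
#' same model, with the same weights, to an analytic pair-correlation
#' curve.
#'
#' @param r bin-center distances, nm.
#' @param g pair-correlation values.
#' @param expected per-bin weights (expected CSR pair counts).
#' @param psf_sigma optional PSF width bound anchor, nm.
#' @param fit_r_max largest distance entering the fit, nm.
#' @return list with `converged`, `A_psf`, `sigma`, `A_c`, `xi`,
#'   `baseline`, `deviance`, `info`.
#' @export
fit_pc_model <- function(r, g, expected, psf_sigma = NULL,
                         fit_r_max = 250) {
  ok <- is.finite(g) & expected > 0 & r > 0 & r <= fit_r_max
  r <- r[ok]; g <- g[ok]; w <- expected[ok]
  excess <- max(g[1] - 1, 0.1)
  resid_fun <- function(p) {
    model <- p[5] + p[1] * exp(-r^2 / (4 * p[2]^2)) + p[3] * exp(-r / p[4])
    sqrt(w) * (model - g)
  }
  sig_lo <- if (is.null(psf_sigma)) 1 else 0.7 * psf_sigma
  sig_hi <- if (is.null(psf_sigma)) 300 else 1.3 * psf_sigma
  sig_0 <- if (is.null(psf_sigma)) 20 else psf_sigma
  xi_max <- min(250, max(r))
  lower <- c(0, sig_lo, 0, 1, 0.5)
  upper <- c(1e6, sig_hi, 1e6, xi_max, 1.5)
  best <- NULL
  for (xi0 in c(30, 60, 120)) {
    start <- c(A_psf = excess / 2, sigma = sig_0, A_c = excess / 2, xi = xi0,
               c0 = 1)
    fit <- try(minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(list(converged = FALSE))
  p <- best$par
  list(converged = best$info %in% 1:4,
       A_psf = p[[1]], sigma = p[[2]], A_c = p[[3]], xi = p[[4]],
       baseline = p[[5]], deviance = best$deviance, info = best$info)
}
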