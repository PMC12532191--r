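#' FCS model: triplet plus mixed free-3D and membrane-2D diffusion
#'
#' Two-component model for a species diffusing freely in 3D (mole fraction
#' `F_1`, diffusion time `tau_D1`) and confined to the membrane plane in 2D
#' (fraction `1 - F_1`, diffusion time `tau_D2`), with a triplet-blinking
#' factor:
#' \deqn{G(\tau) = 1 + \left(1 + \frac{F_T e^{-\tau/\tau_T}}{1-F_T}\right)
#'   \frac{1}{N}\left[F_1 (1+\tau/\tau_{D1})^{-1}
#'   (1+\tau/(S^2\tau_{D1}))^{-1/2} +
#'   (1-F_1)(1+\tau/\tau_{D2})^{-1}\right]}
#'
#' @param tau lag times, s.
#' @param N mean molecules in the effective volume.
#' @param F_T triplet fraction in `[0, 1)`.
#' @param tau_T triplet relaxation time, s.
#' @param F_1 free-3D mole fraction in `[0, 1]`.
#' @param tau_D1 3D diffusion time, s.
#' @param tau_D2 2D membrane diffusion time, s.
#' @param S structure parameter `omega_z / omega_xy`.
#' @return G(tau).
#' @export
fcs_model_two <- function(tau, N, F_T, tau_T, F_1, tau_D1, tau_D2, S) {
  triplet <- 1 + F_T * exp(-tau / tau_T) / (1 - F_T)
  diff3d <- F_1 / ((1 + tau / tau_D1) * sqrt(1 + tau / (S^2 * tau_D1)))
  diff2d <- (1 - F_1) / (1 + tau / tau_D2)
  1 + triplet * (diff3d + diff2d) / N
}

#' FCS model: triplet plus single free-3D diffusion (calibration model)
#'
#' One-component special case of [fcs_model_two()] with `F_1 = 1`.
#'
#' @inheritParams fcs_model_two
#' @param tau_D 3D diffusion time, s.
#' @return G(tau).
#' @export
fcs_model_one <- function(tau, N, F_T, tau_T, tau_D, S) {
  fcs_model_two(tau, N, F_T, tau_T, F_1 = 1,
                tau_D1 = tau_D, tau_D2 = tau_D, S = S)
}

## shared fitting engine: weighted Levenberg-Marquardt with box bounds
fit_fcs_curve <- function(acc, model, free, fixed, start, lower, upper,
                          weighting, lag_range) {
  ok <- acc$lag_s >= lag_range[1] & acc$lag_s <= lag_range[2] &
    is.finite(acc$G)
  tau <- acc$lag_s[ok]; g <- acc$G[ok]
  if (length(tau) < length(free) + 1) stop("too few lags in fit range")
  w <- rep(1, length(tau))
  if (weighting == "sd") {
    s <- acc$sd[ok]
    if (all(is.finite(s)) && all(s > 0)) w <- 1 / s^2
  }
  resid_fun <- function(p) {
    pars <- c(as.list(p), fixed)
    sqrt(w) * (do.call(model, c(list(tau = tau), pars)) - g)
  }
  fit <- minpack.lm::nls.lm(
    par = start[free], lower = lower[free], upper = upper[free],
    fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  est <- c(as.list(fit$par), fixed)
  se <- rep(NA_real_, length(free))
  names(se) <- free
  sm <- try(summary(fit), silent = TRUE)
  if (!inherits(sm, "try-error")) {
    co <- sm$coefficients
    se[rownames(co)] <- co[, "Std. Error"]
  }
  at_bound <- any(abs(unlist(fit$par) - lower[free]) < 1e-12 |
                  abs(unlist(fit$par) - upper[free]) < 1e-12)
  list(estimates = est, se = se, free = free, fixed = names(fixed),
       converged = fit$info %in% 1:4 && !at_bound,
       at_bound = at_bound, info = fit$info,
       deviance = fit$deviance,
       n_lags = length(tau),
       reduced_chisq = fit$deviance / max(1, length(tau) - length(free)))
}

## heuristic initial values from the curve shape
fcs_start_values <- function(acc, lag_range) {
  ok <- acc$lag_s >= lag_range[1] & acc$lag_s <= lag_range[2] &
    is.finite(acc$G)
  tau <- acc$lag_s[ok]; g <- acc$G[ok]
  g0 <- max(g[1] - 1, 1e-3)
  n0 <- 1 / g0
  half <- 1 + g0 / 2
  idx <- which(g <= half)
  tau_half <- if (length(idx) > 0) tau[min(idx)] else tau[length(tau) %/% 2]
  list(N = n0, tau_D = tau_half)
}

#' Fit the one-component (calibration) FCS model
#'
#' Weighted least squares (weights `1/sd^2` across segments when available)
#' of [fcs_model_one()] for `N`, `F_T`, `tau_T`, `tau_D` and `S`.
#' Parameters passed in `fixed` are held at the given values.
#'
#' @param acc an `acc` object from [autocorrelate()] or [acc_curve()].
#' @param fixed named list of parameters to fix (e.g. `list(F_T = 0,
#'   tau_T = 1e-6)` for a triplet-free sample).
#' @param weighting `"sd"` (default; falls back to uniform when no SD is
#'   available) or `"uniform"`.
#' @param lag_range fitted lag window in s.
#' @return object of class `fcs_fit`; see [fit_two_component()].
#' @export
fit_one_component <- function(acc, fixed = list(),
                              weighting = c("sd", "uniform"),
                              lag_range = c(1e-6, 10)) {
  weighting <- match.arg(weighting)
  sv <- fcs_start_values(acc, lag_range)
  start <- list(N = sv$N, F_T = 0.1, tau_T = 5e-6, tau_D = sv$tau_D, S = 5)
  lower <- c(N = 1e-8, F_T = 0, tau_T = 1e-9, tau_D = 1e-9, S = 1)
  upper <- c(N = 1e8, F_T = 0.999, tau_T = 1, tau_D = 100, S = 20)
  free <- setdiff(names(start), names(fixed))
  out <- fit_fcs_curve(acc, fcs_model_one, free, fixed,
                       unlist(start), lower, upper, weighting, lag_range)
  out$model <- "one_component"
  out$acc <- acc
  class(out) <- "fcs_fit"
  out
}

#' Fit the two-component (3D + membrane 2D) FCS model
#'
#' Fits `N`, `F_T`, `tau_T`, `F_1` and `tau_D2` of [fcs_model_two()] with
#' the free-3D diffusion time `tau_D1` and the structure parameter `S` held
#' fixed — `tau_D1` at the value measured for the probe in medium alone
#' (default 213 us) and `S` from the dye calibration — following the
#' calibration-first workflow. A small multi-start over `tau_D2` guards
#' against local minima.
#'
#' @inheritParams fit_one_component
#' @param tau_D1 fixed 3D diffusion time in s (default `213e-6`).
#' @param S fixed structure parameter (default 5).
#' @param fixed additional parameters to fix (e.g. `list(F_T = 0)`).
#' @return object of class `fcs_fit`: list with `estimates` (all model
#'   parameters), `se`, `free`, `fixed`, `converged`, `at_bound`,
#'   `reduced_chisq` and the input curve.
#' @export
fit_two_component <- function(acc, tau_D1 = 213e-6, S = 5, fixed = list(),
                              weighting = c("sd", "uniform"),
                              lag_range = c(1e-6, 10)) {
  weighting <- match.arg(weighting)
  check_scalar(tau_D1, "tau_D1", 0, strict_lower = TRUE)
  check_scalar(S, "S", 1, 20)
  sv <- fcs_start_values(acc, lag_range)
  fixed_all <- c(list(tau_D1 = tau_D1, S = S), fixed)
  lower <- c(N = 1e-8, F_T = 0, tau_T = 1e-9, F_1 = 0, tau_D2 = 1e-9)
  upper <- c(N = 1e8, F_T = 0.999, tau_T = 1, F_1 = 1, tau_D2 = 100)
  best <- NULL
  for (mult in c(0.3, 1, 3, 10)) {
    start <- list(N = sv$N, F_T = 0.1, tau_T = 5e-6, F_1 = 0.5,
                  tau_D2 = sv$tau_D * mult)
    free <- setdiff(names(start), names(fixed_all))
    out <- try(fit_fcs_curve(acc, fcs_model_two, free, fixed_all,
                             unlist(start), lower, upper, weighting,
                             lag_range), silent = TRUE)
    if (inherits(out, "try-error")) next
    if (is.null(best) || out$deviance < best$deviance) best <- out
  }
  if (is.null(best)) stop("two-component fit failed from all starts")
  best$model <- "two_component"
  best$acc <- acc
  class(best) <- "fcs_fit"
  best
}

#' Calibrate the observation volume from a reference-dye fit
#'
#' The lateral radius follows from the known reference diffusion
#' coefficient: `omega_xy = sqrt(4 * D_ref * tau_D_ref)`; the axial radius
#' is `omega_z = omega_xy * S`.
#'
#' @param fit an `fcs_fit` of the one-component model on the reference dye,
#'   or a list with elements `tau_D` and `S`.
#' @param D_ref reference diffusion coefficient in um^2/s (default 330,
#'   the AF647 free-dye value).
#' @return object of class `fcs_calibration`: `omega_xy`, `omega_z` (um),
#'   `S`, `D_ref`, `tau_D_ref` (s).
#' @export
calibrate <- function(fit, D_ref = 330) {
  check_scalar(D_ref, "D_ref", 0, strict_lower = TRUE)
  est <- if (inherits(fit, "fcs_fit")) fit$estimates else fit
  tau_D <- est$tau_D
  S <- est$S
  check_scalar(tau_D, "tau_D", 0, strict_lower = TRUE)
  check_scalar(S, "S", 0, strict_lower = TRUE)
  omega_xy <- sqrt(4 * D_ref * tau_D)
  structure(list(omega_xy = omega_xy, omega_z = omega_xy * S, S = S,
                 D_ref = D_ref, tau_D_ref = tau_D),
            class = "fcs_calibration")
}

#' Membrane surface density, brightness and diffusion coefficient
#'
#' From a two-component fit and the volume calibration:
#' density `rho = (1 - F_1) * N / omega_xy^2` (molecules/um^2), molecular
#' brightness `cpm = mean_intensity / N` (counts/s/molecule), and membrane
#' diffusion coefficient `D = omega_xy^2 / (4 * tau_D2)` (um^2/s).
#'
#' @param fit an `fcs_fit` from [fit_two_component()].
#' @param cal an `fcs_calibration` from [calibrate()].
#' @param mean_intensity average intensity in counts/s; taken from the
#'   fitted curve when omitted.
#' @return list with `rho`, `cpm`, `D_membrane`.
#' @export
derive_membrane_quantities <- function(fit, cal, mean_intensity = NULL) {
  stopifnot(inherits(cal, "fcs_calibration"))
  est <- if (inherits(fit, "fcs_fit")) fit$estimates else fit
  if (is.null(mean_intensity))
    mean_intensity <- fit$acc$mean_intensity
  rho <- (1 - est$F_1) * est$N / cal$omega_xy^2
  cpm <- if (is.null(mean_intensity) || !is.finite(mean_intensity))
    NA_real_ else mean_intensity / est$N
  list(rho = rho, cpm = cpm,
       D_membrane = cal$omega_xy^2 / (4 * est$tau_D2))
}
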