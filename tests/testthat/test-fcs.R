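test_that("multi-tau lag grid has 16 linear lags then doubling spacing", {
  lags <- memquant:::multitau_lags(1000)
  expect_equal(lags[1:16], 1:16)
  expect_equal(diff(lags)[16:23], rep(2, 8))
  expect_true(all(diff(lags) > 0))
  expect_lte(max(lags), 1000)
})

test_that("a constant trace autocorrelates to exactly 1", {
  acc <- autocorrelate(intensity_trace(rep(5, 4000), 1e-3),
                       segment_length = 2)
  expect_equal(acc$G, rep(1, length(acc$G)), tolerance = 1e-14)
})

test_that("the alternating trace matches the hand-computed estimator", {
  acc <- autocorrelate(intensity_trace(rep(c(1, 0), 50), 1),
                       segment_length = 100)
  expect_equal(acc$G[1], 0)
  expect_equal(acc$G[2], 2)
})

test_that("multi-tau G equals the brute-force estimator at shared lags", {
  set.seed(2)
  x <- rpois(10000, 5)
  acc <- autocorrelate(intensity_trace(x, 1e-4), segment_length = 1)
  lags_bins <- round(acc$lag_s / 1e-4)
  expect_lt(max(abs(acc$G - acf_direct(x, lags_bins))), 1e-10)
})

test_that("i.i.d. Poisson noise has G = 1 at all positive lags", {
  set.seed(5)
  acc <- autocorrelate(intensity_trace(rpois(50000, 8), 1e-3),
                       segment_length = 5)
  se <- acc$sd / sqrt(acc$n_segments)
  expect_true(all(abs(acc$G - 1) < 3 * pmax(se, 1e-4)))
})

test_that("zero-mean and bleaching segments are excluded", {
  x <- c(rep(0, 1000), rpois(1000, 5))
  expect_warning(acc <- autocorrelate(intensity_trace(x, 1e-3),
                                      segment_length = 1),
                 "zero mean")
  expect_equal(acc$n_segments, 1L)
  expect_error(suppressWarnings(
    autocorrelate(intensity_trace(rep(0, 2000), 1e-3), segment_length = 1)),
    "all segments")

  # monotone 40% drop in the first segment, stationary second segment
  set.seed(3)
  bleach <- rpois(1000, 50 * seq(1, 0.6, length.out = 1000))
  flat <- rpois(1000, 40)
  acc2 <- autocorrelate(intensity_trace(c(bleach, flat), 1e-3),
                        segment_length = 1)
  expect_equal(acc2$excluded_segments, 1L)
})

test_that("the two-component model nests the one-component model", {
  tau <- 10^seq(-6, 0, length.out = 120)
  g1 <- fcs_model_one(tau, N = 3, F_T = 0.1, tau_T = 4e-6, tau_D = 1e-4,
                      S = 5)
  g2 <- fcs_model_two(tau, N = 3, F_T = 0.1, tau_T = 4e-6, F_1 = 1,
                      tau_D1 = 1e-4, tau_D2 = 7, S = 5)
  expect_equal(g1, g2, tolerance = 1e-12)
  # F_T = 0 disables the triplet factor
  g3 <- fcs_model_one(tau, N = 3, F_T = 0, tau_T = 4e-6, tau_D = 1e-4, S = 5)
  g4 <- 1 + (1 / 3) / ((1 + tau / 1e-4) * sqrt(1 + tau / (25 * 1e-4)))
  expect_equal(g3, g4, tolerance = 1e-12)
  # amplitude limit
  expect_equal(fcs_model_one(1e-12, N = 4, F_T = 0, tau_T = 1e-6,
                             tau_D = 1e-4, S = 5), 1 + 1 / 4,
               tolerance = 1e-6)
})

test_that("one-component fit round-trips a noiseless model curve", {
  tau <- 10^seq(-6, 0, length.out = 200)
  g <- fcs_model_one(tau, N = 2, F_T = 0.15, tau_T = 5e-6, tau_D = 25e-6,
                     S = 5)
  fit <- fit_one_component(acc_curve(tau, g))
  truth <- c(N = 2, F_T = 0.15, tau_T = 5e-6, tau_D = 25e-6, S = 5)
  for (p in names(truth))
    expect_lt(abs(fit$estimates[[p]] - truth[[p]]) / truth[[p]], 1e-3)
  expect_true(fit$converged)
})

test_that("two-component fits agree with one-component fits when F_1 = 1", {
  tau <- 10^seq(-6, 0, length.out = 200)
  g <- fcs_model_one(tau, N = 2, F_T = 0.15, tau_T = 5e-6, tau_D = 213e-6,
                     S = 5)
  acc <- acc_curve(tau, g)
  f1 <- fit_one_component(acc, fixed = list(tau_D = 213e-6, S = 5))
  f2 <- fit_two_component(acc, tau_D1 = 213e-6, S = 5)
  expect_lt(abs(f2$estimates$F_1 - 1), 1e-6)
  for (p in c("N", "F_T", "tau_T"))
    expect_lt(abs(f1$estimates[[p]] - f2$estimates[[p]]), 1e-6)
})

test_that("calibration follows the closed forms and round-trips", {
  cal <- calibrate(list(tau_D = 25e-6, S = 5), D_ref = 330)
  expect_equal(cal$omega_xy, sqrt(0.033), tolerance = 1e-12)
  expect_equal(cal$omega_z, sqrt(0.033) * 5, tolerance = 1e-12)
  expect_equal(cal$omega_xy^2 / (4 * 330), 25e-6, tolerance = 1e-15)
})

test_that("membrane quantities follow the defining arithmetic", {
  cal <- structure(list(omega_xy = 0.2, omega_z = 1, S = 5, D_ref = 330,
                        tau_D_ref = 0.2^2 / (4 * 330)),
                   class = "fcs_calibration")
  fit <- structure(list(estimates = list(N = 2, F_1 = 0.2, tau_D2 = 1e-2),
                        acc = list(mean_intensity = NA_real_)),
                   class = "fcs_fit")
  dq <- derive_membrane_quantities(fit, cal, mean_intensity = 3500)
  expect_equal(dq$rho, 0.8 * 2 / 0.04)  # 40 molecules/um^2
  expect_equal(dq$D_membrane, 0.04 / (4 * 1e-2))
  fit7 <- structure(list(estimates = list(N = 7, F_1 = 1, tau_D2 = 1e-2),
                         acc = list(mean_intensity = NA_real_)),
                    class = "fcs_fit")
  dq7 <- derive_membrane_quantities(fit7, cal, mean_intensity = 3500)
  expect_equal(dq7$cpm, 500)  # 3.5 kHz / 7 molecules
  expect_equal(dq7$rho, 0)    # fully unbound
})

test_that("membrane D is invariant under consistent time-unit changes", {
  # same fit expressed in seconds and in milliseconds
  cal_s <- calibrate(list(tau_D = 25e-6, S = 5), D_ref = 330)
  cal_ms <- calibrate(list(tau_D = 25e-3, S = 5), D_ref = 330e-3)
  fit_s <- structure(list(estimates = list(N = 2, F_1 = 0.2,
                                           tau_D2 = 1e-2)),
                     class = "fcs_fit")
  fit_ms <- structure(list(estimates = list(N = 2, F_1 = 0.2,
                                            tau_D2 = 1e1)),
                      class = "fcs_fit")
  d_s <- derive_membrane_quantities(fit_s, cal_s, 1000)$D_membrane
  d_ms <- derive_membrane_quantities(fit_ms, cal_ms, 1)$D_membrane
  expect_equal(d_s, d_ms * 1e3, tolerance = 1e-12)
})

test_that("fitted N scales with the simulated particle number", {
  fit_n <- function(n2d, seeds) {
    vapply(seeds, function(sd) {
      ft <- fcs_truth(d_2d = 2, n_particles_2d = n2d, omega_xy = 0.2,
                      brightness = 3e4, bin_time = 5e-4, duration = 30,
                      box_size = 3)
      acc <- autocorrelate(simulate_fcs_trace(ft, sd), segment_length = 10)
      fit <- fit_two_component(acc, tau_D1 = 213e-6, S = 5,
                               fixed = list(F_T = 0, tau_T = 1e-6, F_1 = 0),
                               lag_range = c(5e-4, 0.2))
      fit$estimates$N
    }, numeric(1))
  }
  n_lo <- mean(fit_n(135, 1:5))
  n_hi <- mean(fit_n(270, 1:5))
  expect_lt(abs(n_hi / n_lo - 2), 0.3)
})

test_that("one-component fits recover D from pure 3D simulations", {
  # tau_D = omega^2 / (4 D) = 5 ms at D = 2 um^2/s, omega = 0.2 um; the
  # fit window stays inside the periodic-box validity bound (L/2pi)^2/D
  d_err <- vapply(1:2, function(sd) {
    ft <- fcs_truth(d_2d = 0, d_3d = 2, n_particles_2d = 0,
                    n_particles_3d = 480, omega_xy = 0.2, omega_z = 0.6,
                    brightness = 3e4, bin_time = 1e-4, duration = 40,
                    box_size = 2, triplet_fraction = 0)
    acc <- autocorrelate(simulate_fcs_trace(ft, sd), segment_length = 10)
    fit <- fit_one_component(acc, fixed = list(F_T = 0, tau_T = 1e-6,
                                               S = 3),
                             lag_range = c(1e-4, 0.05))
    d_est <- 0.2^2 / (4 * fit$estimates$tau_D)
    abs(d_est - 2) / 2
  }, numeric(1))
  expect_lt(mean(d_err), 0.20)
})
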