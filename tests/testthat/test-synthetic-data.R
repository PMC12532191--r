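test_that("no-blinking, noise-free simulation reproduces molecule positions", {
  pos <- cbind(c(500, 1500, 2500, 800, 1800), c(400, 900, 2200, 2600, 1400))
  tr <- smlm_truth(field_size = 3, n_frames = 100, molecule_positions = pos,
                   alpha_true = 1, localization_precision = 0,
                   drift_velocity = c(0, 0), n_fiducials = 0)
  s <- simulate_smlm(tr, seed = 1)
  tab <- s$localizations
  expect_equal(nrow(tab), 5L)
  expect_setequal(tab$x_nm, pos[, 1])
  expect_setequal(tab$y_nm, pos[, 2])
  expect_false(any(tab$is_fiducial))
})

test_that("background molecule count follows the Poisson expectation", {
  tr <- smlm_truth(field_size = 4, n_frames = 50, cluster_density = 0,
                   background_density = 10, alpha_true = 1,
                   localization_precision = 0, drift_velocity = c(0, 0),
                   n_fiducials = 0)
  counts <- vapply(1:100, function(sd)
    simulate_smlm(tr, seed = sd)$truth$n_molecules, numeric(1))
  se <- sqrt(160 / 100)  # Poisson(160), 100 replicates
  expect_lt(abs(mean(counts) - 160), 3 * se)
})

test_that("blinking yields alpha localizations per molecule on average", {
  tr <- smlm_truth(field_size = 30, n_frames = 20000, cluster_density = 0,
                   background_density = 11.2, alpha_true = 3.3,
                   dark_time_scale = 10, localization_precision = 10,
                   drift_velocity = c(0, 0), n_fiducials = 0)
  s <- simulate_smlm(tr, seed = 7)
  realized <- nrow(s$localizations) / s$truth$n_molecules
  expect_lt(abs(realized - 3.3) / 3.3, 0.05)
})

test_that("fiducials appear in every frame and are flagged", {
  tr <- smlm_truth(field_size = 3, n_frames = 500, cluster_density = 0,
                   background_density = 5, alpha_true = 1, n_fiducials = 3)
  s <- simulate_smlm(tr, seed = 2)
  fid <- s$localizations[s$localizations$is_fiducial, ]
  expect_equal(nrow(fid), 3L * 500L)
  expect_equal(sort(unique(fid$frame)), 0:499)
  expect_true(!is.unsorted(s$localizations$frame))
})

test_that("simulation refuses absurd localization volumes", {
  tr <- smlm_truth(field_size = 100, n_frames = 6e6, background_density = 50,
                   cluster_density = 0, n_fiducials = 3)
  expect_error(simulate_smlm(tr, 1), "1e7")
})

test_that("same seed gives bit-identical outputs, different seeds differ", {
  tr <- smlm_truth(field_size = 3, n_frames = 300, cluster_density = 3,
                   background_density = 10, n_fiducials = 2)
  a <- simulate_smlm(tr, seed = 11)
  b <- simulate_smlm(tr, seed = 11)
  c <- simulate_smlm(tr, seed = 12)
  expect_identical(a$localizations, b$localizations)
  expect_false(identical(a$localizations, c$localizations))

  ft <- fcs_truth(duration = 1, n_particles_2d = 20, box_size = 2)
  expect_identical(simulate_fcs_trace(ft, 3)$counts,
                   simulate_fcs_trace(ft, 3)$counts)

  tt <- transient_truth(noise_sd = 2)
  expect_identical(simulate_ratio_trace(tt, 4), simulate_ratio_trace(tt, 4))
})

test_that("simulation functions leave the caller's RNG state untouched", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_fcs_trace(fcs_truth(duration = 0.5,
                                         n_particles_2d = 10,
                                         box_size = 2), 5))
  expect_identical(.Random.seed, before)
})

test_that("zero brightness gives an all-zero trace", {
  ft <- fcs_truth(brightness = 0, duration = 1, n_particles_2d = 50,
                  box_size = 2)
  expect_true(all(simulate_fcs_trace(ft, 1)$counts == 0))
})

test_that("an immobile particle at the focus emits Poisson counts", {
  ft <- fcs_truth(d_2d = 0, n_particles_2d = 1, n_particles_3d = 0,
                  brightness = 1e4, bin_time = 1e-3, duration = 20,
                  box_size = 2, triplet_fraction = 0)
  trc <- simulate_fcs_trace(ft, 7, init_2d = matrix(c(0, 0), 1))
  lambda <- 1e4 * 1e-3
  se <- sqrt(lambda / nrow(trc))
  expect_lt(abs(mean(trc$counts) - lambda), 3 * se)
})

test_that("trace size guard trips on absurd durations", {
  expect_error(simulate_fcs_trace(fcs_truth(duration = 2e5, bin_time = 1e-6,
                                            box_size = 2), 1),
               "1e8")
})

test_that("noise-free ratio trace reproduces baseline and amplitude", {
  tt <- transient_truth(baseline_ratio = 1, amplitude = 0, noise_sd = 0,
                        bleach_rate_bound = 0, bleach_rate_unbound = 0)
  tr <- simulate_ratio_trace(tt, 1)
  frr <- tr$I_bound / tr$I_unbound
  expect_equal(frr, rep(1, tt$n_frames), tolerance = 1e-12)

  tt2 <- transient_truth(baseline_ratio = 1, amplitude = 0.5, noise_sd = 0)
  tr2 <- simulate_ratio_trace(tt2, 1)
  rt <- compute_frr(tr2$I_bound, tr2$I_unbound, stim_frame = tt2$stim_frame)
  expect_equal(rt$normalized_amplitude, 0.5, tolerance = 1e-10)
})

test_that("noisy ratio traces recover the true baseline on average", {
  tt <- transient_truth(baseline_ratio = 1.2, amplitude = 0.5, noise_sd = 2)
  bl <- vapply(1:50, function(sd) {
    tr <- simulate_ratio_trace(tt, sd)
    compute_frr(tr$I_bound, tr$I_unbound, stim_frame = 4)$baseline
  }, numeric(1))
  se <- sd(bl) / sqrt(length(bl))
  expect_lt(abs(mean(bl) - 1.2), 3 * se)
})

test_that("GP ring images split channel intensity by the prescribed GP", {
  img0 <- simulate_gp_image(0, noise_sd = 0, seed = 1)
  expect_equal(img0$ch1, img0$ch2, tolerance = 1e-12)

  img1 <- simulate_gp_image(1, noise_sd = 0, seed = 1)
  expect_true(all(img1$ch2 == 0))
  expect_gt(max(img1$ch1), 0)
})

test_that("GP is recovered from noisy ring images", {
  img <- simulate_gp_image(0.3, noise_sd = 4, seed = 2)  # 2% of ring peak
  gp <- cell_gp_from_image(img$ch1, img$ch2, img$center, img$radius_px,
                           n_profiles = 10)
  expect_lt(abs(gp$gp_mean - 0.3), 0.02)
})
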