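make_table <- function(frame, x, y, prec = 15, fid = FALSE) {
  n <- length(frame)
  data.frame(frame = as.integer(frame), x_nm = x, y_nm = y,
             precision_nm = rep_len(prec, n),
             is_fiducial = rep_len(fid, n))
}

test_that("drift correction is the identity for drift-free input", {
  tr <- smlm_truth(field_size = 3, n_frames = 500, cluster_density = 0,
                   background_density = 10, alpha_true = 1,
                   localization_precision = 0, drift_velocity = c(0, 0),
                   n_fiducials = 2)
  s <- simulate_smlm(tr, 3)
  out <- correct_drift(s$localizations)
  expect_equal(out$x_nm, s$localizations$x_nm, tolerance = 1e-9)
  expect_equal(out$y_nm, s$localizations$y_nm, tolerance = 1e-9)
})

test_that("constructed linear drift is removed to sub-nm residuals", {
  n_frames <- 60000
  f <- 0:(n_frames - 1)
  tab <- make_table(f, 1000 + 0.001 * f, 2000 - 0.0005 * f, prec = 0,
                    fid = TRUE)
  out <- correct_drift(tab)
  rms <- sqrt(mean((out$x_nm - mean(out$x_nm))^2 +
                   (out$y_nm - mean(out$y_nm))^2))
  expect_lt(rms, 1)
  drift <- attr(out, "drift")
  expect_lt(sqrt(mean((drift$dx_nm - 0.001 * f)^2)), 1)
})

test_that("drift trajectory is recovered from noisy fiducials", {
  tr <- smlm_truth(field_size = 4, n_frames = 20000, cluster_density = 0,
                   background_density = 10, alpha_true = 3.3,
                   dark_time_scale = 10, localization_precision = 15,
                   drift_velocity = c(0.003, -0.002), n_fiducials = 3)
  s <- simulate_smlm(tr, 4)
  out <- correct_drift(s$localizations)
  d <- attr(out, "drift")
  err <- sqrt(mean((d$dx_nm - 0.003 * d$frame)^2 +
                   (d$dy_nm + 0.002 * d$frame)^2))
  expect_lt(err, 5)
})

test_that("absence of fiducials is an explicit error, never a pass-through", {
  tab <- make_table(0:99, runif(100, 0, 1000), runif(100, 0, 1000))
  expect_error(correct_drift(tab), "no fiducial")
})

test_that("unflagged persistent beads are detected by persistence", {
  f <- 0:999
  bead <- make_table(f, 500 + rnorm(1000, 0, 5), 600 + rnorm(1000, 0, 5))
  sparse <- make_table(seq(0, 999, by = 50), runif(20, 2000, 9000),
                       runif(20, 2000, 9000))
  tab <- rbind(bead, sparse)
  tab <- tab[order(tab$frame), ]
  flag <- detect_fiducials(tab)
  expect_equal(sum(flag), 1000L)
  out <- correct_drift(tab)  # flag-free table, detection path
  expect_true(any(out$is_fiducial))
})

test_that("photophysics estimation matches hand enumeration", {
  tab <- make_table(c(1, 2, 10, 5), c(0, 0, 0, 5000), c(0, 0, 0, 5000))
  # only 2 groups -> insufficient; embed in a sparse field of singletons
  extra <- make_table(seq_len(20) * 7, seq_len(20) * 1e4 + 2e5,
                      seq_len(20) * 1e4 + 2e5)
  ph <- estimate_photophysics(rbind(tab, extra), frame_exposure = 1)
  # 24 localizations in 22 groups: {1,2,10}, {5}, 20 singletons
  expect_equal(ph$alpha, 24 / 22)
  expect_equal(ph$max_dark_frames, 8)
  expect_equal(ph$max_dark_time, 8)

  one_each <- make_table(1:30, seq_len(30) * 1e3, seq_len(30) * 1e3)
  expect_equal(estimate_photophysics(one_each)$alpha, 1)
})

test_that("photophysics estimation needs at least ten probe groups", {
  tab <- make_table(1:5, seq_len(5) * 1e4, seq_len(5) * 1e4)
  expect_error(estimate_photophysics(tab), "insufficient")
})

test_that("alpha is recovered from a sparse blinking field", {
  tr <- smlm_truth(field_size = 60, n_frames = 20000, cluster_density = 0,
                   background_density = 0.3, alpha_true = 3.3,
                   dark_time_scale = 10, localization_precision = 15,
                   drift_velocity = c(0, 0), n_fiducials = 0)
  s <- simulate_smlm(tr, 5)
  ph <- estimate_photophysics(s$localizations)
  expect_lt(abs(ph$alpha - 3.3) / 3.3, 0.05)
})

test_that("molecule counting divides localizations by alpha", {
  set.seed(1)
  tab <- make_table(1:330, runif(330, 0, 1000), runif(330, 0, 1000))
  rr <- suppressWarnings(roi(0, 0, 1000))
  cnt <- count_molecules(tab, rr, photophysics(alpha = 3.3))
  expect_equal(cnt$n_molecules, 100)
  expect_equal(cnt$density, 100)

  empty <- make_table(integer(0), numeric(0), numeric(0))
  expect_warning(cnt0 <- count_molecules(empty, rr, photophysics(3.3)),
                 "empty")
  expect_equal(cnt0$density, 0)
})

test_that("counting is exact for alpha = 1 with zero precision", {
  tr <- smlm_truth(field_size = 4, n_frames = 100, cluster_density = 0,
                   background_density = 25, alpha_true = 1,
                   localization_precision = 0, drift_velocity = c(0, 0),
                   n_fiducials = 0)
  s <- simulate_smlm(tr, 8)
  rr <- roi(0, 0, 4000)
  cnt <- count_molecules(s$localizations, rr, photophysics(alpha = 1))
  expect_equal(cnt$n_molecules, s$truth$n_molecules)
})

test_that("molecule density is recovered under blinking", {
  tr <- smlm_truth(field_size = 4, n_frames = 20000, cluster_density = 0,
                   background_density = 60, alpha_true = 3.3,
                   dark_time_scale = 10, localization_precision = 15,
                   drift_velocity = c(0, 0), n_fiducials = 0)
  dens <- vapply(1:5, function(sd) {
    s <- simulate_smlm(tr, sd)
    rr <- roi(500, 500, 3000)
    count_molecules(s$localizations, rr, photophysics(alpha = 3.3))$density
  }, numeric(1))
  expect_lt(abs(mean(dens) - 60) / 60, 0.10)
})

test_that("binned g(r) equals the brute-force pair-count oracle", {
  set.seed(42)
  n <- 200
  tab <- make_table(rep(0L, n), runif(n, 0, 3000), runif(n, 0, 3000))
  rr <- roi(0, 0, 3000)
  pc <- pair_correlation(tab, rr, bin_width = 10, r_max = 500)
  oracle_counts <- pair_count_direct(tab$x_nm, tab$y_nm, 10, 50)
  expect_equal(pc$counts, oracle_counts)
  expect_equal(pc$g, oracle_counts / pc$expected_pairs)
})

test_that("g(r) of CSR points is 1 within sampling error", {
  rr <- roi(0, 0, 3000)
  set.seed(7)
  gmat <- vapply(1:100, function(i) {
    tab <- make_table(rep(0L, 500), runif(500, 0, 3000), runif(500, 0, 3000))
    pair_correlation(tab, rr)$g
  }, numeric(50))
  m <- rowMeans(gmat)
  se <- apply(gmat, 1, sd) / sqrt(100)
  z <- abs(m - 1) / pmax(se, 1e-6)
  # per-bin 3 SE with a Bonferroni-style family allowance over 50 bins
  expect_true(all(z < 3.9))
  expect_gte(mean(z < 3), 0.9)
})

test_that("cluster radius estimates are consistent with the population fit", {
  xi_star <- population_xi(kappa = 5e-6, mu = 10, sigma = 30,
                           lam_bg = 20e-6, alpha = 3.3, prec = 15)
  tr <- smlm_truth(field_size = 4, n_frames = 20000, cluster_density = 5,
                   molecules_per_cluster_mean = 10, cluster_sigma = 30,
                   background_density = 20, alpha_true = 3.3,
                   dark_time_scale = 10, localization_precision = 15,
                   drift_velocity = c(0, 0), n_fiducials = 0)
  xis <- vapply(1:3, function(sd) {
    s <- simulate_smlm(tr, sd)
    pair_correlation(s$localizations, roi(500, 500, 3000))$cluster_radius
  }, numeric(1))
  expect_lt(abs(mean(xis) - xi_star) / xi_star, 0.25)
})

test_that("cluster assignment matches hand enumeration", {
  set.seed(1)
  th <- runif(6) * 2 * pi
  rad <- 25 * sqrt(runif(6))
  pos <- rbind(cbind(500 + rad * cos(th), 500 + rad * sin(th)),
               cbind(c(1500, 2500, 500), c(500, 1500, 2500)))
  cl <- assign_clusters(pos, cluster_radius = 50, area_um2 = 9)
  expect_equal(cl$n_clusters, 1L)
  expect_equal(cl$molecules_per_cluster, 6)
  expect_equal(cl$clustered_fraction, 6 / 9)

  empty <- assign_clusters(matrix(numeric(0), ncol = 2), 50, area_um2 = 1)
  expect_equal(empty$n_clusters, 0L)
  expect_equal(empty$molecules_per_cluster, 0)
  expect_equal(empty$clusters_per_area, 0)

  expect_error(assign_clusters(pos, cluster_radius = 0), "cluster_radius")
})

test_that("cluster reports are translation invariant", {
  set.seed(3)
  pos <- cbind(runif(400, 0, 3000), runif(400, 0, 3000))
  pos <- rbind(pos, cbind(rnorm(40, 700, 30), rnorm(40, 900, 30)))
  a <- assign_clusters(pos, 40, area_um2 = 9)
  b <- assign_clusters(pos + 313.17, 40, area_um2 = 9)
  expect_equal(a$n_clusters, b$n_clusters)
  expect_equal(a$molecules_per_cluster, b$molecules_per_cluster)
  expect_equal(a$clustered_fraction, b$clustered_fraction)
  expect_equal(a$clusters_per_area, b$clusters_per_area)
})

test_that("reported molecules per cluster grows with the simulated mean", {
  res <- vapply(c(6, 10, 16), function(mu) {
    vals <- vapply(1:3, function(sd) {
      tr <- do.call(smlm_truth, scaled_smlm_pars(
        field_size = 3, molecules_per_cluster_mean = mu, n_frames = 3000))
      s <- simulate_smlm(tr, sd)
      out <- analyze_smlm_cell(s$localizations, 3, alpha = 3.3, n_rois = 1)
      out$molecules_per_cluster
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(res) > 0))
})

test_that("spatio-temporal merging collapses repeated localizations", {
  # two molecules, bursts within the dark-time gate
  tab <- make_table(c(0, 5, 9, 0, 7),
                    c(100, 110, 95, 5000, 5010),
                    c(100, 108, 101, 5000, 4995))
  mol <- merge_localizations(tab, radius = 100, max_dark_frames = 20)
  expect_equal(nrow(mol), 2L)
  expect_equal(sort(mol$n_localizations), c(2L, 3L))
  # a temporal gate of zero keeps same-frame-only linkage
  mol2 <- merge_localizations(tab, radius = 100, max_dark_frames = 2)
  expect_gt(nrow(mol2), 2L)
})

test_that("ROI tiling keeps the densest tiles", {
  set.seed(2)
  dense <- make_table(rep(0L, 400), runif(400, 0, 3000), runif(400, 0, 3000))
  sparse <- make_table(rep(0L, 20), runif(20, 3000, 6000),
                       runif(20, 0, 3000))
  rois <- tile_rois(rbind(dense, sparse), field_size = 6, roi_side = 3000,
                    n_keep = 1)
  expect_equal(rois[[1]]$x, 0)
  expect_equal(rois[[1]]$y, 0)
})
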