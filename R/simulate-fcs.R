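#' Ground truth for a synthetic FCS measurement
#'
#' Mixed free 3D diffusion (probe in medium) and 2D membrane diffusion
#' (probe bound in the focal plane) observed through a 3D Gaussian detection
#' volume, with triplet blinking and Poisson photon statistics.
#'
#' @param d_2d membrane diffusion coefficient, um^2/s.
#' @param d_3d solution diffusion coefficient, um^2/s.
#' @param n_particles_2d,n_particles_3d particle counts in the simulation box.
#' @param triplet_fraction stationary triplet (dark) fraction in `[0, 1)`.
#' @param triplet_tau triplet relaxation time, s.
#' @param omega_xy,omega_z lateral and axial 1/e^2 radii of the detection
#'   volume, um.
#' @param brightness counts/s per molecule at the focus.
#' @param bin_time sampling bin, s.
#' @param duration trace duration, s.
#' @param box_size lateral box side, um (must be >= 10 * omega_xy). The
#'   periodic box reproduces free diffusion only for lags well below
#'   `(box_size / (2 pi))^2 / D`; fits should stay inside that window.
#' @return object of class `fcs_truth`.
#' @export
fcs_truth <- function(d_2d = 0.5, d_3d = 50, n_particles_2d = 540,
                      n_particles_3d = 0, triplet_fraction = 0,
                      triplet_tau = 5e-6, omega_xy = 0.2, omega_z = 1.0,
                      brightness = 3e4, bin_time = 1e-3, duration = 200,
                      box_size = 6) {
  check_scalar(d_2d, "d_2d", 0)
  check_scalar(d_3d, "d_3d", 0)
  check_scalar(n_particles_2d, "n_particles_2d", 0)
  check_scalar(n_particles_3d, "n_particles_3d", 0)
  check_scalar(triplet_fraction, "triplet_fraction", 0, 1 - 1e-9)
  check_scalar(triplet_tau, "triplet_tau", 0, strict_lower = TRUE)
  check_scalar(omega_xy, "omega_xy", 0, strict_lower = TRUE)
  check_scalar(omega_z, "omega_z", 0, strict_lower = TRUE)
  check_scalar(brightness, "brightness", 0)
  check_scalar(bin_time, "bin_time", 0, strict_lower = TRUE)
  check_scalar(duration, "duration", 0, strict_lower = TRUE)
  check_scalar(box_size, "box_size", 0, strict_lower = TRUE)
  if (box_size < 10 * omega_xy)
    stop("box_size must be at least 10 * omega_xy")
  structure(list(
    d_2d = d_2d, d_3d = d_3d,
    n_particles_2d = as.integer(n_particles_2d),
    n_particles_3d = as.integer(n_particles_3d),
    triplet_fraction = triplet_fraction, triplet_tau = triplet_tau,
    omega_xy = omega_xy, omega_z = omega_z, brightness = brightness,
    bin_time = bin_time, duration = duration, box_size = box_size
  ), class = "fcs_truth")
}

#' Simulate a photon-count intensity trace
#'
#' Brownian dynamics with one step per bin (per-axis SD `sqrt(2 D dt)`) in a
#' periodic box; 2D particles stay in the focal plane. Detection weight is
#' the Gaussian profile `exp(-2 r_xy^2/omega_xy^2) exp(-2 z^2/omega_z^2)`;
#' triplet blinking gates emission as a two-state telegraph process; photon
#' counts per bin are Poisson with mean `brightness * sum(weights) * dt`.
#'
#' @param truth an [fcs_truth()] object.
#' @param seed integer seed.
#' @param init_2d,init_3d optional initial positions (um, centered on the
#'   focus); used by tests that need particles at known positions.
#' @return object of class `intensity_trace`: data.frame `time_s, counts`
#'   with attributes `bin_time` and `truth`.
#' @export
simulate_fcs_trace <- function(truth, seed, init_2d = NULL, init_3d = NULL) {
  stopifnot(inherits(truth, "fcs_truth"))
  n_bins <- round(truth$duration / truth$bin_time)
  if (n_bins > 1e8) stop("trace would exceed 1e8 bins; reduce duration")
  box_z <- max(truth$box_size, 10 * truth$omega_z)
  counts <- with_seed(seed, fcs_simulate_counts(
    n_bins = as.integer(n_bins), bin_time = truth$bin_time,
    n2d = truth$n_particles_2d, n3d = truth$n_particles_3d,
    d2d = truth$d_2d, d3d = truth$d_3d,
    box_xy = truth$box_size, box_z = box_z,
    omega_xy = truth$omega_xy, omega_z = truth$omega_z,
    triplet_fraction = truth$triplet_fraction,
    triplet_tau = truth$triplet_tau,
    brightness = truth$brightness,
    init2d = if (is.null(init_2d)) NULL else as.matrix(init_2d),
    init3d = if (is.null(init_3d)) NULL else as.matrix(init_3d)
  ))
  out <- data.frame(time_s = (seq_len(n_bins) - 1) * truth$bin_time,
                    counts = counts)
  attr(out, "bin_time") <- truth$bin_time
  attr(out, "truth") <- truth
  class(out) <- c("intensity_trace", "data.frame")
  out
}

#' Build an intensity trace from a plain counts vector
#'
#' @param counts non-negative counts (or intensities) per bin.
#' @param bin_time bin width in s.
#' @return `intensity_trace` object.
#' @export
intensity_trace <- function(counts, bin_time) {
  check_scalar(bin_time, "bin_time", 0, strict_lower = TRUE)
  stopifnot(is.numeric(counts), all(is.finite(counts)))
  out <- data.frame(time_s = (seq_along(counts) - 1) * bin_time,
                    counts = as.numeric(counts))
  attr(out, "bin_time") <- bin_time
  class(out) <- c("intensity_trace", "data.frame")
  out
}
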