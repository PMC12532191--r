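#' Ground truth for a synthetic Fura Red calcium transient
#'
#' Two-channel (Ca-bound / Ca-unbound) intensity series with exponential
#' photobleaching, a depolarization-evoked transient (linear rise, then
#' exponential decay) and additive Gaussian noise. The true Fura Red ratio
#' is `baseline_ratio + amplitude * shape(t)` with `shape` peaking at 1.
#'
#' @param baseline_ratio true FRr before stimulation.
#' @param amplitude true FRr increase at the transient peak.
#' @param rise_frames frames of linear rise to the peak.
#' @param decay_frames exponential decay constant of the transient, frames.
#' @param bleach_rate_bound,bleach_rate_unbound per-frame bleaching rates
#'   of the two channels (equal by default: the ratio cancels common bleach).
#' @param noise_sd additive Gaussian noise SD on each channel (intensity
#'   units; channel base intensity is 100).
#' @param stim_frame 0-based frame of K+ depolarization (>= 4: the first
#'   four frames are pre-stimulus by convention).
#' @param n_frames total frames (55 by default: 4 pre + 51 post stimulus).
#' @return object of class `transient_truth`.
#' @export
transient_truth <- function(baseline_ratio = 1.0, amplitude = 0.5,
                            rise_frames = 3, decay_frames = 10,
                            bleach_rate_bound = 0.002,
                            bleach_rate_unbound = 0.002,
                            noise_sd = 2, stim_frame = 4, n_frames = 55) {
  check_scalar(baseline_ratio, "baseline_ratio", 0, strict_lower = TRUE)
  check_scalar(amplitude, "amplitude", 0)
  check_scalar(rise_frames, "rise_frames", 1)
  check_scalar(decay_frames, "decay_frames", 1)
  check_scalar(bleach_rate_bound, "bleach_rate_bound", 0)
  check_scalar(bleach_rate_unbound, "bleach_rate_unbound", 0)
  check_scalar(noise_sd, "noise_sd", 0)
  check_scalar(stim_frame, "stim_frame", 4)
  check_scalar(n_frames, "n_frames", stim_frame + 1)
  structure(list(
    baseline_ratio = baseline_ratio, amplitude = amplitude,
    rise_frames = as.integer(rise_frames),
    decay_frames = as.integer(decay_frames),
    bleach_rate_bound = bleach_rate_bound,
    bleach_rate_unbound = bleach_rate_unbound,
    noise_sd = noise_sd, stim_frame = as.integer(stim_frame),
    n_frames = as.integer(n_frames)
  ), class = "transient_truth")
}

#' Simulate a two-channel Fura Red time series
#'
#' The transient multiplies the bound channel by `sqrt(FRr_true / baseline)`
#' and divides the unbound channel by the same factor, so the channel ratio
#' equals the prescribed true FRr exactly before noise and differential
#' bleaching are applied.
#'
#' @param truth a [transient_truth()] object.
#' @param seed integer seed.
#' @return data.frame `frame, I_bound, I_unbound` with attributes `truth`
#'   and `frr_true` (the noise-free ratio per frame).
#' @export
simulate_ratio_trace <- function(truth, seed) {
  stopifnot(inherits(truth, "transient_truth"))
  with_seed(seed, {
    f <- 0:(truth$n_frames - 1L)
    shape <- numeric(truth$n_frames)
    post <- f >= truth$stim_frame
    tpost <- f[post] - truth$stim_frame
    peak <- truth$rise_frames - 1L
    shape[post] <- ifelse(
      tpost <= peak,
      (tpost + 1) / truth$rise_frames,
      exp(-(tpost - peak) / truth$decay_frames)
    )
    frr_true <- truth$baseline_ratio + truth$amplitude * shape

    base_i <- 100
    fac <- sqrt(frr_true / truth$baseline_ratio)
    bound <- base_i * sqrt(truth$baseline_ratio) * fac *
      exp(-truth$bleach_rate_bound * f)
    unbound <- base_i / sqrt(truth$baseline_ratio) / fac *
      exp(-truth$bleach_rate_unbound * f)
    out <- data.frame(
      frame = f,
      I_bound = bound + rnorm(truth$n_frames, 0, truth$noise_sd),
      I_unbound = unbound + rnorm(truth$n_frames, 0, truth$noise_sd)
    )
    attr(out, "truth") <- truth
    attr(out, "frr_true") <- frr_true
    out
  })
}

#' Simulate a two-channel membrane ring image with prescribed GP
#'
#' A circular cell whose membrane is a ring of Gaussian radial cross-section;
#' the two spectral channels split the ring intensity as `(1 + GP)/2` and
#' `(1 - GP)/2`, so the generalized polarization at the ring equals
#' `gp_true` exactly before noise.
#'
#' @param gp_true true GP in `[-1, 1]`.
#' @param cell_radius cell radius, um.
#' @param ring_width full width of the membrane ring, um.
#' @param noise_sd additive Gaussian noise SD (intensity units; ring peak
#'   total intensity is 200).
#' @param seed integer seed.
#' @param pixel_size um per pixel.
#' @return list with `ch1`, `ch2` (matrices, rows = y), `center` (pixel
#'   coordinates of the cell center), `radius_px`, `gp_true`, `pixel_size`.
#' @export
simulate_gp_image <- function(gp_true, cell_radius = 5, ring_width = 0.5,
                              noise_sd = 0, seed = 1, pixel_size = 0.1) {
  check_scalar(gp_true, "gp_true", -1, 1)
  check_scalar(cell_radius, "cell_radius", 0, strict_lower = TRUE)
  check_scalar(ring_width, "ring_width", 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  with_seed(seed, {
    margin <- 4 * ring_width
    side <- ceiling(2 * (cell_radius + margin) / pixel_size)
    center <- (side + 1) / 2
    xs <- matrix(rep(seq_len(side), each = side), nrow = side)   # column index
    ys <- matrix(rep(seq_len(side), times = side), nrow = side)  # row index
    r <- sqrt((xs - center)^2 + (ys - center)^2) * pixel_size
    peak <- 200
    w <- ring_width / 2.355  # FWHM -> sigma
    total <- peak * exp(-(r - cell_radius)^2 / (2 * w^2))
    total[r < cell_radius - ring_width] <- 0.05 * peak  # dim interior
    ch1 <- total * (1 + gp_true) / 2
    ch2 <- total * (1 - gp_true) / 2
    if (noise_sd > 0) {
      ch1 <- ch1 + matrix(rnorm(side^2, 0, noise_sd), side)
      ch2 <- ch2 + matrix(rnorm(side^2, 0, noise_sd), side)
    }
    list(ch1 = ch1, ch2 = ch2, center = c(center, center),
         radius_px = cell_radius / pixel_size, gp_true = gp_true,
         pixel_size = pixel_size)
  })
}
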