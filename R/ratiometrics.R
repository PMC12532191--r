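#' Fura Red ratio trace with baseline and transient amplitude
#'
#' Computes the per-frame Fura Red ratio
#' `FRr(t) = I_bound(t) / I_unbound(t)` — the ratio of the Ca-bound to the
#' Ca-unbound channel, which cancels photobleaching common to both channels.
#' The baseline is the mean FRr over the pre-stimulus frames (the first
#' `n_baseline` frames); the amplitude is the FRr at the first local maximum
#' at or after the stimulation frame minus the baseline. Peak location is
#' found on an optional 3-frame median-smoothed copy; the amplitude is read
#' from the raw ratio at that frame. If no local maximum occurs before the
#' series ends, the global post-stimulus maximum is used and flagged.
#'
#' @param bound,unbound equal-length intensity series of the Ca-bound and
#'   Ca-unbound channels.
#' @param stim_frame 0-based stimulation frame (>= `n_baseline`).
#' @param n_baseline number of pre-stimulus frames defining the baseline
#'   (default 4).
#' @param smooth apply 3-frame median smoothing before peak detection.
#' @return object of class `ratio_trace`: list with `frr` (per frame),
#'   `baseline`, `amplitude`, `normalized_amplitude`, `peak_frame`
#'   (0-based), `peak_is_local` and `excluded_frames`.
#' @export
compute_frr <- function(bound, unbound, stim_frame, n_baseline = 4,
                        smooth = TRUE) {
  stopifnot(length(bound) == length(unbound))
  check_scalar(stim_frame, "stim_frame", n_baseline)
  n <- length(bound)
  if (n <= stim_frame) stop("series ends before the stimulation frame")
  bad <- !(unbound > 0)
  if (any(bad)) warning(sum(bad), " frame(s) with non-positive unbound",
                        " intensity excluded")
  frr <- ifelse(bad, NA_real_, bound / unbound)
  baseline <- mean(frr[seq_len(n_baseline)], na.rm = TRUE)

  s <- frr
  if (smooth && n >= 3) {
    filled <- s
    if (anyNA(filled)) {
      idx <- which(!is.na(filled))
      filled <- stats::approx(idx, filled[idx], xout = seq_len(n),
                              rule = 2)$y
    }
    s <- runmed(filled, 3)
  }
  post <- (stim_frame + 1):n  # 1-based indices at/after the stimulus
  peak <- NA_integer_
  for (i in post) {
    if (i <= 1 || i >= n) next
    # smoothing can flatten a sharp peak into a plateau, so the detector
    # accepts plateau shoulders and then reads the raw maximum nearby
    if (!is.na(s[i]) && s[i] >= s[i - 1] && s[i] >= s[i + 1]) {
      win <- max(i - 1, post[1]):min(i + 1, n)
      peak <- win[which.max(frr[win])]
      break
    }
  }
  peak_is_local <- !is.na(peak)
  if (!peak_is_local) peak <- post[which.max(frr[post])]
  amplitude <- frr[peak] - baseline
  out <- list(frr = frr, baseline = baseline, amplitude = amplitude,
              normalized_amplitude = amplitude / baseline,
              peak_frame = peak - 1L, peak_is_local = peak_is_local,
              excluded_frames = which(bad) - 1L,
              stim_frame = stim_frame, n_baseline = n_baseline)
  class(out) <- "ratio_trace"
  out
}

#' Generalized polarization from a membrane line profile
#'
#' The membrane position along the line is the index maximizing the summed
#' channel intensity (both channels are read at the same point), and
#' `GP = (I_1 - I_2) / (I_1 + I_2)` there, where channel 1 is the
#' ordered-phase (560-580 nm) band and channel 2 the disordered-phase
#' (640-660 nm) band. Lower GP means a more fluid membrane.
#'
#' @param profile_ch1,profile_ch2 same-length intensity profiles sampled
#'   along one line crossing the membrane.
#' @return list with `gp`, `position` (index of the membrane point),
#'   `I1`, `I2`.
#' @export
compute_gp <- function(profile_ch1, profile_ch2) {
  stopifnot(length(profile_ch1) == length(profile_ch2),
            length(profile_ch1) >= 1)
  total <- profile_ch1 + profile_ch2
  pos <- which.max(total)
  i1 <- profile_ch1[pos]; i2 <- profile_ch2[pos]
  if (i1 + i2 == 0) stop("undefined GP: zero total intensity at membrane")
  list(gp = (i1 - i2) / (i1 + i2), position = pos, I1 = i1, I2 = i2)
}

#' Per-cell GP as the mean over membrane positions
#'
#' @param gps numeric vector of per-position GP values (conventionally 4-10
#'   positions per cell).
#' @return list with `gp_mean` and `n_positions`.
#' @export
cell_gp <- function(gps) {
  stopifnot(length(gps) >= 1)
  list(gp_mean = mean(gps), n_positions = length(gps))
}

#' Extract co-registered line profiles from two channel images
#'
#' Samples both channels by bilinear interpolation at unit-pixel spacing
#' along the segment from `p0` to `p1` (pixel coordinates, `c(x, y)` with
#' x = column, y = row, 1-based).
#'
#' @param image_ch1,image_ch2 numeric matrices (rows = y).
#' @param p0,p1 segment endpoints in pixel coordinates.
#' @return list with `profile_ch1`, `profile_ch2`, `x`, `y` (sample
#'   positions).
#' @export
extract_line_profile <- function(image_ch1, image_ch2, p0, p1) {
  stopifnot(all(dim(image_ch1) == dim(image_ch2)))
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("degenerate zero-length line segment")
  n <- floor(len) + 1L
  tt <- seq(0, len, length.out = n) / len
  xs <- p0[1] + tt * (p1[1] - p0[1])
  ys <- p0[2] + tt * (p1[2] - p0[2])
  if (any(xs < 1 | xs > ncol(image_ch1) | ys < 1 | ys > nrow(image_ch1)))
    stop("line endpoints outside the image")
  list(profile_ch1 = bilinear_sample(image_ch1, xs, ys),
       profile_ch2 = bilinear_sample(image_ch2, xs, ys),
       x = xs, y = ys)
}

bilinear_sample <- function(img, xs, ys) {
  x0 <- pmin(floor(xs), ncol(img) - 1L); x1 <- x0 + 1L
  y0 <- pmin(floor(ys), nrow(img) - 1L); y1 <- y0 + 1L
  fx <- xs - x0; fy <- ys - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x1)] * fx * (1 - fy) +
    img[cbind(y1, x0)] * (1 - fx) * fy +
    img[cbind(y1, x1)] * fx * fy
}
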