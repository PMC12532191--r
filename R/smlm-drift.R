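#' Detect fiducial beads by persistence
#'
#' A fiducial is a spatial track (single-linkage within `radius`) that is
#' present in at least `min_persistence` of all frames.
#'
#' @param table localization table (`frame, x_nm, y_nm, ...`).
#' @param radius linkage radius in nm.
#' @param min_persistence minimum fraction of frames a track must appear in.
#' @param n_frames total frame count; inferred from the table if missing.
#' @return logical vector flagging fiducial localizations.
#' @export
detect_fiducials <- function(table, radius = 100, min_persistence = 0.9,
                             n_frames = NULL) {
  if (nrow(table) == 0) return(logical(0))
  if (is.null(n_frames)) n_frames <- max(table$frame) + 1L
  lab <- spatial_linkage(table$x_nm, table$y_nm, radius)
  per_track <- tapply(table$frame, lab, function(f) length(unique(f)))
  fid_labs <- as.integer(names(per_track)[per_track >= min_persistence * n_frames])
  lab %in% fid_labs
}

#' Correct stage drift using fiducial beads
#'
#' Per-frame drift is the mean displacement of the fiducials from their
#' first-frame positions, smoothed with a centered moving average
#' (`smooth_window` frames, shrinking at the edges), linearly interpolated
#' over frames with no fiducial, and subtracted from every localization.
#' Fiducials are retained in the output, still flagged.
#'
#' @param table localization table with an `is_fiducial` column; if no
#'   localization is flagged, fiducials are detected by persistence
#'   (>= 90 percent of frames within a 100 nm track).
#' @param smooth_window moving-average window in frames.
#' @return drift-corrected table with attribute `drift`, a data.frame
#'   `frame, dx_nm, dy_nm` of the estimated (smoothed) drift.
#' @export
correct_drift <- function(table, smooth_window = 100) {
  stopifnot(all(c("frame", "x_nm", "y_nm") %in% names(table)))
  if (is.null(table$is_fiducial) || !any(table$is_fiducial)) {
    flag <- detect_fiducials(table)
    if (!any(flag)) stop("no fiducial found: flag fiducials or include a bead",
                         " persisting in >= 90% of frames")
    table$is_fiducial <- flag
  }
  fid <- table[table$is_fiducial, , drop = FALSE]

  # separate beads: anchors are the bead positions in the earliest frame
  # (beads sit far apart relative to drift, so nearest-anchor assignment
  # is exact and O(n) in the number of fiducial localizations)
  anchors <- fid[fid$frame == min(fid$frame), c("x_nm", "y_nm"), drop = FALSE]
  lab <- nearest_center(cbind(fid$x_nm, fid$y_nm), as.matrix(anchors))$index
  n_frames <- max(table$frame) + 1L
  dx_sum <- dy_sum <- cnt <- numeric(n_frames)
  for (l in unique(lab)) {
    tr <- fid[lab == l, , drop = FALSE]
    tr <- tr[order(tr$frame), , drop = FALSE]
    # reference = robust estimate of the first-frame position (mean over the
    # first smoothing window), so localization noise does not bias the origin
    nref <- min(smooth_window, nrow(tr))
    ref <- c(mean(tr$x_nm[seq_len(nref)]), mean(tr$y_nm[seq_len(nref)]))
    # one observation per frame per bead (average duplicates)
    fx <- rowsum(tr$x_nm, tr$frame); fy <- rowsum(tr$y_nm, tr$frame)
    fn <- rowsum(rep(1, nrow(tr)), tr$frame)
    fr <- as.integer(rownames(fx)) + 1L
    dx_sum[fr] <- dx_sum[fr] + fx[, 1] / fn[, 1] - ref[1]
    dy_sum[fr] <- dy_sum[fr] + fy[, 1] / fn[, 1] - ref[2]
    cnt[fr] <- cnt[fr] + 1
  }
  seen <- cnt > 0
  if (!any(seen)) stop("no fiducial found")
  dx <- dy <- rep(NA_real_, n_frames)
  dx[seen] <- dx_sum[seen] / cnt[seen]
  dy[seen] <- dy_sum[seen] / cnt[seen]
  if (!all(seen)) {  # interpolate frames without a fiducial observation
    idx <- which(seen)
    dx <- stats::approx(idx, dx[idx], xout = seq_len(n_frames), rule = 2)$y
    dy <- stats::approx(idx, dy[idx], xout = seq_len(n_frames), rule = 2)$y
  }
  dx <- moving_average(dx, smooth_window)
  dy <- moving_average(dy, smooth_window)

  out <- table
  fidx <- out$frame + 1L
  out$x_nm <- out$x_nm - dx[fidx]
  out$y_nm <- out$y_nm - dy[fidx]
  attr(out, "drift") <- data.frame(frame = 0:(n_frames - 1L),
                                   dx_nm = dx, dy_nm = dy)
  out
}
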