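#' Estimate fluorophore photophysics from a sparse single-probe field
#'
#' On a field sparse enough that each diffraction-limited spot holds at most
#' one probe, localizations are grouped into per-probe tracks by spatial
#' single linkage (`linkage_radius`). The mean number of localizations per
#' track estimates `alpha`, the mean appearances per probe; the collection
#' of within-track dark gaps (differences between consecutive appearance
#' frames) yields the maximum dark time as the `gap_quantile` of all gaps
#' (default 1 = the maximum).
#'
#' @param table localization table; fiducials (if flagged) are excluded.
#' @param gap_quantile quantile of the dark-gap distribution reported as
#'   `max_dark_time` (1 = maximum).
#' @param linkage_radius spatial linkage radius in nm.
#' @param frame_exposure exposure per frame in s (converts gaps to seconds).
#' @return object of class `photophysics`: list with `alpha`,
#'   `max_dark_time` (s), `max_dark_frames`, `n_groups`, `n_gaps`.
#' @export
estimate_photophysics <- function(table, gap_quantile = 1,
                                  linkage_radius = 100,
                                  frame_exposure = 0.01) {
  check_scalar(gap_quantile, "gap_quantile", 0, 1)
  if (!is.null(table$is_fiducial)) table <- table[!table$is_fiducial, ]
  if (nrow(table) == 0) stop("insufficient data: empty table")
  lab <- spatial_linkage(table$x_nm, table$y_nm, linkage_radius)
  n_groups <- max(lab)
  if (n_groups < 10) stop("insufficient data: fewer than 10 probe groups")
  alpha <- nrow(table) / n_groups
  gaps <- unlist(lapply(split(table$frame, lab), function(f) {
    if (length(f) < 2) return(NULL)
    diff(sort(f))
  }), use.names = FALSE)
  max_dark_frames <- if (length(gaps) > 0)
    as.numeric(quantile(gaps, gap_quantile, type = 1)) else NA_real_
  structure(list(
    alpha = alpha,
    max_dark_time = max_dark_frames * frame_exposure,
    max_dark_frames = max_dark_frames,
    n_groups = n_groups, n_gaps = length(gaps)
  ), class = "photophysics")
}

#' Construct a photophysics model from known values
#'
#' @param alpha mean localizations per probe (>= 1).
#' @param max_dark_time maximum dark time in s.
#' @return object of class `photophysics`.
#' @export
photophysics <- function(alpha = 3.3, max_dark_time = 250) {
  check_scalar(alpha, "alpha", 1)
  check_scalar(max_dark_time, "max_dark_time", 0, strict_lower = TRUE)
  structure(list(alpha = alpha, max_dark_time = max_dark_time),
            class = "photophysics")
}

#' Merge localizations into per-molecule representative positions
#'
#' Spatio-temporal single linkage: localizations within `radius` of each
#' other and separated by at most `max_dark_frames` frames belong to one
#' molecule; the representative position is the centroid of the group.
#' Valid on sparse fields; on dense clustered fields neighbouring molecules
#' chain together, so cluster analysis should prefer alpha-division counting
#' (see [assign_clusters()]).
#'
#' @param table localization table (fiducials excluded if flagged).
#' @param radius spatial linkage radius, nm.
#' @param max_dark_frames temporal gate in frames (`Inf` = spatial only).
#' @return data.frame `x_nm, y_nm, n_localizations, first_frame`.
#' @export
merge_localizations <- function(table, radius = 100, max_dark_frames = Inf) {
  if (!is.null(table$is_fiducial)) table <- table[!table$is_fiducial, ]
  if (nrow(table) == 0)
    return(data.frame(x_nm = numeric(0), y_nm = numeric(0),
                      n_localizations = integer(0), first_frame = integer(0)))
  gate <- if (is.finite(max_dark_frames)) max_dark_frames else -1
  lab <- spatial_linkage(table$x_nm, table$y_nm, radius,
                         frame = as.integer(table$frame), max_gap = gate)
  data.frame(
    x_nm = as.numeric(tapply(table$x_nm, lab, mean)),
    y_nm = as.numeric(tapply(table$y_nm, lab, mean)),
    n_localizations = as.integer(tapply(table$x_nm, lab, length)),
    first_frame = as.integer(tapply(table$frame, lab, min))
  )
}
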