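#' Square region of interest
#'
#' @param x,y origin (lower-left corner) in nm.
#' @param side side length in nm. The conventional ROI area for membrane
#'   quantification is 9-16 um^2; a warning is issued outside that range.
#' @return object of class `roi`.
#' @export
roi <- function(x, y, side) {
  check_scalar(side, "side", 0, strict_lower = TRUE)
  area_um2 <- (side / 1000)^2
  if (area_um2 < 9 || area_um2 > 16)
    warning(sprintf("ROI area %.2f um^2 outside the conventional 9-16 um^2",
                    area_um2))
  structure(list(x = x, y = y, side = side, area_um2 = area_um2),
            class = "roi")
}

roi_subset <- function(table, roi) {
  # half-open membership [origin, origin + side)
  table[table$x_nm >= roi$x & table$x_nm < roi$x + roi$side &
        table$y_nm >= roi$y & table$y_nm < roi$y + roi$side, , drop = FALSE]
}

#' Blinking-corrected molecule counting in an ROI
#'
#' Divides the localization count inside the ROI by `alpha`, the mean number
#' of localizations per fluorescent probe, to obtain the number of detected
#' molecules; reports the surface density in molecules/um^2. Fractional
#' molecule counts are permitted.
#'
#' @param table drift-corrected localization table; fiducials are excluded.
#' @param roi an [roi()] object.
#' @param phys a [photophysics()] model (its `alpha` is used).
#' @return list with `n_localizations`, `n_molecules`, `density`
#'   (molecules/um^2) and `area_um2`.
#' @export
count_molecules <- function(table, roi, phys) {
  stopifnot(inherits(roi, "roi"), inherits(phys, "photophysics"))
  if (!is.null(table$is_fiducial)) table <- table[!table$is_fiducial, ]
  sub <- roi_subset(table, roi)
  n <- nrow(sub)
  if (n == 0) warning("empty ROI: density 0")
  mol <- n / phys$alpha
  list(n_localizations = n, n_molecules = mol,
       density = mol / roi$area_um2, area_um2 = roi$area_um2)
}

#' Tile a field into candidate ROIs and keep the densest
#'
#' Automated stand-in for manual ROI placement: the field is tiled with
#' square tiles of side `roi_side` and the `n_keep` densest tiles
#' (localization count) are returned, emulating the practice of placing
#' three to four 9-16 um^2 ROIs on the cell.
#'
#' @param table localization table (fiducials excluded for ranking).
#' @param field_size field side in um.
#' @param roi_side tile side in nm (default 3000 nm -> 9 um^2).
#' @param n_keep number of ROIs to keep.
#' @return list of [roi()] objects.
#' @export
tile_rois <- function(table, field_size, roi_side = 3000, n_keep = 4) {
  if (!is.null(table$is_fiducial)) table <- table[!table$is_fiducial, ]
  L <- field_size * 1000
  n_tiles <- max(1L, floor(L / roi_side))
  origins <- expand.grid(x = (seq_len(n_tiles) - 1) * roi_side,
                         y = (seq_len(n_tiles) - 1) * roi_side)
  counts <- mapply(function(ox, oy) {
    sum(table$x_nm >= ox & table$x_nm < ox + roi_side &
        table$y_nm >= oy & table$y_nm < oy + roi_side)
  }, origins$x, origins$y)
  keep <- order(counts, decreasing = TRUE)[seq_len(min(n_keep, nrow(origins)))]
  lapply(keep, function(i) suppressWarnings(
    roi(origins$x[i], origins$y[i], roi_side)))
}
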