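#' Read and write the standard file layouts
#'
#' Localization tables are CSV with header
#' `frame,x_nm,y_nm,precision_nm,is_fiducial`; intensity traces are CSV
#' `time_s,counts`; ground truth travels as a sidecar JSON next to each
#' dataset; two-channel images are multi-page TIFF with a JSON sidecar
#' documenting the channel order.
#'
#' @param table localization data.frame.
#' @param path file path.
#' @name memquant-io
NULL

#' @rdname memquant-io
#' @export
write_localizations <- function(table, path) {
  stopifnot(all(c("frame", "x_nm", "y_nm", "precision_nm", "is_fiducial")
                %in% names(table)))
  data.table::fwrite(table, path)
  invisible(path)
}

#' @rdname memquant-io
#' @export
read_localizations <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  stopifnot(all(c("frame", "x_nm", "y_nm") %in% names(tab)))
  if (is.null(tab$is_fiducial)) tab$is_fiducial <- FALSE
  tab$is_fiducial <- as.logical(tab$is_fiducial)
  tab[order(tab$frame), , drop = FALSE]
}

#' @rdname memquant-io
#' @param trace an `intensity_trace`.
#' @export
write_trace <- function(trace, path) {
  data.table::fwrite(data.frame(time_s = trace$time_s,
                                counts = trace$counts), path)
  invisible(path)
}

#' @rdname memquant-io
#' @export
read_trace <- function(path) {
  tab <- as.data.frame(data.table::fread(path))
  stopifnot(all(c("time_s", "counts") %in% names(tab)), nrow(tab) >= 2)
  intensity_trace(tab$counts, bin_time = tab$time_s[2] - tab$time_s[1])
}

#' @rdname memquant-io
#' @param truth any ground-truth object (`smlm_truth`, `fcs_truth`,
#'   `transient_truth`, or a plain list).
#' @export
write_truth_json <- function(truth, path) {
  obj <- unclass(truth)
  obj$.class <- class(truth)[1]
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname memquant-io
#' @export
read_truth_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- obj$.class
  obj$.class <- NULL
  for (f in c("cluster_centers", "molecule_positions", "fiducial_positions"))
    if (!is.null(obj[[f]])) obj[[f]] <- as.matrix(obj[[f]])
  if (!is.null(cls) && cls != "list") class(obj) <- cls
  obj
}

#' @rdname memquant-io
#' @param image list with `ch1`, `ch2` matrices (e.g. [simulate_gp_image()]).
#' @param channels channel descriptions written to the sidecar JSON.
#' @export
write_two_channel_tiff <- function(image, path,
                                   channels = c("I_560_580", "I_640_660")) {
  mx <- max(image$ch1, image$ch2, 1)
  # 16-bit storage is defined on [0, 1]; negative noise excursions clip to 0
  clip01 <- function(m) pmin(pmax(m / mx, 0), 1)
  tiff::writeTIFF(list(clip01(image$ch1), clip01(image$ch2)), path,
                  bits.per.sample = 16)
  meta <- list(channels = as.list(channels), scale = mx,
               pixel_size = image$pixel_size)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname memquant-io
#' @export
read_two_channel_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stopifnot(length(pages) >= 2)
  meta_path <- paste0(path, ".json")
  scale <- 1
  meta <- NULL
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$scale)) scale <- meta$scale
  }
  list(ch1 = pages[[1]] * scale, ch2 = pages[[2]] * scale, meta = meta)
}
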