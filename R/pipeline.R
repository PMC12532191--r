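#' Build a run configuration
#'
#' A run config drives an end-to-end simulate / analyze / full run over a
#' cohort of synthetic cells grouped into named conditions, one of which is
#' the control. Each condition carries ground-truth parameter overrides for
#' the enabled modules; each module block carries its analysis parameters.
#'
#' @param mode `"simulate"` (write data), `"analyze"` (read data and write
#'   reports) or `"full"` (both).
#' @param seed integer master seed (mandatory unless mode is `"analyze"`);
#'   per-cell seeds are derived as `seed + 1000 * condition_index + cell`.
#' @param output_dir directory for the data and report bundle.
#' @param conditions named list of condition parameter lists; each may hold
#'   blocks `smlm`, `fcs`, `ratio`, `gp` with ground-truth overrides.
#' @param control name of the control condition (first condition by
#'   default).
#' @param n_cells cells per condition.
#' @param modules named list of analysis-parameter blocks; a module runs
#'   when its name appears here (default: `smlm` only).
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("full", "simulate", "analyze"),
                       seed = NULL, output_dir,
                       conditions, control = names(conditions)[1],
                       n_cells = 10,
                       modules = list(smlm = list())) {
  mode <- match.arg(mode)
  if (mode != "analyze" && is.null(seed))
    stop("seed is mandatory in simulate/full mode")
  stopifnot(is.list(conditions), length(conditions) >= 1,
            !is.null(names(conditions)))
  if (!control %in% names(conditions))
    stop("control condition '", control, "' not among conditions")
  check_scalar(n_cells, "n_cells", 1)
  structure(list(mode = mode, seed = seed, output_dir = output_dir,
                 conditions = conditions, control = control,
                 n_cells = as.integer(n_cells), modules = modules),
            class = "run_config")
}

#' Load a run configuration from YAML or JSON
#'
#' @param path config file (`.yaml`/`.yml` or `.json`).
#' @return a [run_config()] object.
#' @export
load_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
         else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, obj)
}

cell_seed <- function(seed, cond_idx, cell) seed + 1000L * cond_idx + cell

cell_dir <- function(config, cond, cell)
  file.path(config$output_dir, "data", cond, sprintf("cell_%03d", cell))

#' Execute a run configuration
#'
#' Simulates and/or analyzes every cell of every condition for the enabled
#' modules, then runs the statistics stage: a split-resampling sufficiency
#' test per condition and metric, and comparisons of every condition against
#' the control (Welch t-test for qSMLM metrics, Mann-Whitney for FCS and
#' ratiometric metrics). Writes per-module metric tables
#' (`metrics_<module>.csv`), a `summary.json` with all test results, and a
#' `provenance.json` (config hash, seeds, package version). Any stage
#' failure aborts with a stage-tagged error.
#'
#' @param config a [run_config()] object.
#' @return invisibly, a list with `metrics` (per-module data.frames),
#'   `stats` and `output_dir`.
#' @export
run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  conds <- names(config$conditions)
  mods <- names(config$modules)

  if (config$mode %in% c("simulate", "full")) {
    tryCatch(
      for (ci in seq_along(conds)) {
        for (cell in seq_len(config$n_cells)) {
          simulate_cell(config, conds[ci], ci, cell)
        }
      },
      error = function(e) stage_error("simulate", conditionMessage(e))
    )
  }
  if (config$mode == "simulate") {
    write_provenance(config)
    return(invisible(list(metrics = NULL, stats = NULL,
                          output_dir = config$output_dir)))
  }

  metrics <- list()
  tryCatch(
    for (m in mods) {
      rows <- list()
      for (ci in seq_along(conds)) {
        for (cell in seq_len(config$n_cells)) {
          row <- analyze_cell(config, conds[ci], ci, cell, m)
          row$condition <- conds[ci]
          row$cell <- cell
          rows[[length(rows) + 1L]] <- row
        }
      }
      metrics[[m]] <- do.call(rbind, rows)
    },
    error = function(e) {
      if (inherits(e, "memquant_stage_error")) stop(e)
      stage_error("analyze", conditionMessage(e))
    }
  )

  stats <- tryCatch(cohort_statistics(config, metrics),
                    error = function(e) stage_error("stats",
                                                    conditionMessage(e)))

  for (m in names(metrics)) {
    data.table::fwrite(metrics[[m]],
                       file.path(config$output_dir,
                                 sprintf("metrics_%s.csv", m)))
  }
  jsonlite::write_json(stats, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  write_provenance(config)
  invisible(list(metrics = metrics, stats = stats,
                 output_dir = config$output_dir))
}

simulate_cell <- function(config, cond, ci, cell) {
  dir <- cell_dir(config, cond, cell)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pars <- config$conditions[[cond]]
  sd0 <- cell_seed(config$seed, ci, cell)
  if ("smlm" %in% names(config$modules)) {
    truth <- do.call(smlm_truth, pars$smlm %||% list())
    sim <- simulate_smlm(truth, seed = sd0)
    write_localizations(sim$localizations,
                        file.path(dir, "localizations.csv"))
    write_truth_json(sim$truth, file.path(dir, "smlm_truth.json"))
  }
  if ("fcs" %in% names(config$modules)) {
    truth <- do.call(fcs_truth, pars$fcs %||% list())
    tr <- simulate_fcs_trace(truth, seed = sd0 + 1L)
    write_trace(tr, file.path(dir, "trace.csv"))
    write_truth_json(truth, file.path(dir, "fcs_truth.json"))
  }
  if ("ratio" %in% names(config$modules)) {
    truth <- do.call(transient_truth, pars$ratio %||% list())
    tr <- simulate_ratio_trace(truth, seed = sd0 + 2L)
    data.table::fwrite(tr, file.path(dir, "ratio.csv"))
    write_truth_json(truth, file.path(dir, "ratio_truth.json"))
  }
  if ("gp" %in% names(config$modules)) {
    gpars <- pars$gp %||% list()
    gpars$seed <- sd0 + 3L
    img <- do.call(simulate_gp_image, gpars)
    write_two_channel_tiff(img, file.path(dir, "gp.tiff"))
    write_truth_json(list(gp_true = img$gp_true, center = img$center,
                          radius_px = img$radius_px,
                          pixel_size = img$pixel_size),
                     file.path(dir, "gp_truth.json"))
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

require_file <- function(path) {
  if (!file.exists(path))
    stage_error("analyze", paste("missing input file:", path))
  path
}

analyze_cell <- function(config, cond, ci, cell, module) {
  dir <- cell_dir(config, cond, cell)
  mp <- config$modules[[module]] %||% list()
  switch(module,
    smlm = {
      tab <- read_localizations(require_file(
        file.path(dir, "localizations.csv")))
      truth <- read_truth_json(file.path(dir, "smlm_truth.json"))
      analyze_smlm_cell(tab,
                        field_size = truth$field_size,
                        alpha = mp$alpha %||% truth$alpha_true,
                        roi_side = mp$roi_side %||% 3000,
                        n_rois = mp$n_rois %||% 4,
                        bin_width = mp$bin_width %||% 10,
                        r_max = mp$r_max %||% 500)
    },
    fcs = {
      tr <- read_trace(require_file(file.path(dir, "trace.csv")))
      analyze_fcs_cell(tr,
                       segment_length = mp$segment_length %||% 20,
                       tau_D1 = mp$tau_D1 %||% 213e-6,
                       S = mp$S %||% 5,
                       omega_xy = mp$omega_xy %||% 0.2,
                       fix_triplet = isTRUE(mp$fix_triplet))
    },
    ratio = {
      tr <- as.data.frame(data.table::fread(require_file(
        file.path(dir, "ratio.csv"))))
      truth <- read_truth_json(file.path(dir, "ratio_truth.json"))
      rt <- compute_frr(tr$I_bound, tr$I_unbound,
                        stim_frame = truth$stim_frame,
                        n_baseline = mp$n_baseline %||% 4)
      data.frame(baseline = rt$baseline, amplitude = rt$amplitude,
                 normalized_amplitude = rt$normalized_amplitude)
    },
    gp = {
      img <- read_two_channel_tiff(require_file(file.path(dir, "gp.tiff")))
      truth <- read_truth_json(file.path(dir, "gp_truth.json"))
      gp <- cell_gp_from_image(img$ch1, img$ch2, truth$center,
                               truth$radius_px,
                               n_profiles = mp$n_profiles %||% 8)
      data.frame(gp_mean = gp$gp_mean, n_positions = gp$n_positions)
    },
    stop("unknown module: ", module)
  )
}

#' Per-cell qSMLM metric extraction
#'
#' Drift-corrects the table, places the densest `n_rois` tiles of side
#' `roi_side`, and reports per-cell means over ROIs of: detected density
#' (molecules/um^2, alpha-corrected), pair-correlation cluster radius (nm),
#' molecules per cluster, clusters per um^2 and clustered fraction.
#'
#' @param table localization table.
#' @param field_size field side, um.
#' @param alpha localizations per molecule used for counting.
#' @param roi_side ROI side, nm.
#' @param n_rois ROIs to keep.
#' @param bin_width,r_max pair-correlation binning, nm.
#' @return one-row data.frame of per-cell metrics.
#' @export
analyze_smlm_cell <- function(table, field_size, alpha = 3.3,
                              roi_side = 3000, n_rois = 4,
                              bin_width = 10, r_max = 500) {
  tab <- correct_drift(table)
  tab <- tab[!tab$is_fiducial, , drop = FALSE]
  phys <- photophysics(alpha = alpha)
  rois <- tile_rois(tab, field_size, roi_side = roi_side, n_keep = n_rois)
  rows <- lapply(rois, function(rr) {
    cnt <- count_molecules(tab, rr, phys)
    pc <- pair_correlation(tab, rr, bin_width = bin_width, r_max = r_max)
    xi <- if (isTRUE(pc$converged)) pc$cluster_radius else NA_real_
    cl <- if (is.finite(xi)) {
      sub <- roi_subset(tab, rr)
      assign_clusters(cbind(sub$x_nm, sub$y_nm), cluster_radius = xi,
                      area_um2 = rr$area_um2, alpha = alpha)
    } else NULL
    data.frame(
      detected_density = cnt$density,
      cluster_radius = xi,
      molecules_per_cluster = if (is.null(cl)) NA_real_
                              else cl$molecules_per_cluster,
      clusters_per_area = if (is.null(cl)) NA_real_ else cl$clusters_per_area,
      clustered_fraction = if (is.null(cl)) NA_real_ else cl$clustered_fraction
    )
  })
  per_roi <- do.call(rbind, rows)
  out <- as.data.frame(lapply(per_roi, mean, na.rm = TRUE))
  out$n_rois <- length(rois)
  out
}

#' Per-cell FCS metric extraction
#'
#' @param trace an `intensity_trace`.
#' @param segment_length autocorrelation segment length, s.
#' @param tau_D1 fixed free-3D diffusion time, s.
#' @param S fixed structure parameter.
#' @param omega_xy lateral radius from calibration, um.
#' @param fix_triplet fix the triplet fraction to zero (for triplet-free
#'   acquisitions).
#' @param lag_range fitted lag window in s; the default starts at the
#'   sampling bin and ends well inside the validity window of the periodic
#'   simulation box.
#' @return one-row data.frame with `N`, `F_1`, `tau_D2`, `D_membrane`,
#'   `rho`, `cpm`.
#' @export
analyze_fcs_cell <- function(trace, segment_length = 20, tau_D1 = 213e-6,
                             S = 5, omega_xy = 0.2, fix_triplet = FALSE,
                             lag_range = c(1e-3, 0.5)) {
  acc <- autocorrelate(trace, segment_length = segment_length)
  fixed <- if (fix_triplet) list(F_T = 0, tau_T = 1e-6) else list()
  fit <- fit_two_component(acc, tau_D1 = tau_D1, S = S, fixed = fixed,
                           lag_range = lag_range)
  cal <- structure(list(omega_xy = omega_xy, omega_z = omega_xy * S, S = S,
                        D_ref = NA_real_,
                        tau_D_ref = omega_xy^2 / (4 * 330)),
                   class = "fcs_calibration")
  dq <- derive_membrane_quantities(fit, cal)
  data.frame(N = fit$estimates$N, F_1 = fit$estimates$F_1,
             tau_D2 = fit$estimates$tau_D2, D_membrane = dq$D_membrane,
             rho = dq$rho, cpm = dq$cpm)
}

#' Per-cell GP from a two-channel ring image
#'
#' Extracts `n_profiles` radial line profiles through the membrane ring at
#' equally spaced angles and averages the per-profile GP values.
#'
#' @param ch1,ch2 channel matrices.
#' @param center cell center, pixel coordinates `c(x, y)`.
#' @param radius_px cell radius in pixels.
#' @param n_profiles number of radial profiles (4-10 conventionally).
#' @return list with `gp_mean`, `n_positions`, `gp_values`.
#' @export
cell_gp_from_image <- function(ch1, ch2, center, radius_px, n_profiles = 8) {
  angles <- seq(0, 2 * pi, length.out = n_profiles + 1)[-(n_profiles + 1)]
  reach <- min(radius_px * 1.5,
               min(center[1] - 1, center[2] - 1,
                   ncol(ch1) - center[1], nrow(ch1) - center[2]))
  gps <- vapply(angles, function(a) {
    p1 <- center + reach * c(cos(a), sin(a))
    pr <- extract_line_profile(ch1, ch2, center, p1)
    compute_gp(pr$profile_ch1, pr$profile_ch2)$gp
  }, numeric(1))
  c(cell_gp(gps), list(gp_values = gps))
}

cohort_statistics <- function(config, metrics) {
  control <- config$control
  conds <- names(config$conditions)
  test_for <- function(module) {
    if (module %in% c("fcs", "ratio", "gp")) "mann_whitney" else "welch_t"
  }
  out <- list()
  for (m in names(metrics)) {
    tab <- metrics[[m]]
    mcols <- setdiff(names(tab), c("condition", "cell", "n_rois",
                                   "n_positions"))
    split_tests <- list()
    comparisons <- list()
    for (col in mcols) {
      for (cond in conds) {
        v <- tab[[col]][tab$condition == cond]
        v <- v[is.finite(v)]
        key <- paste(cond, col, sep = ".")
        if (length(v) >= 4) {
          st <- split_sufficiency_test(v, seed = (config$seed %||% 0) + 7L)
          split_tests[[key]] <- list(p_split = st$p_split,
                                     sufficient = st$sufficient)
        }
        if (cond != control) {
          ctrl <- tab[[col]][tab$condition == control]
          ctrl <- ctrl[is.finite(ctrl)]
          if (length(v) >= 2 && length(ctrl) >= 2) {
            cmp <- compare_groups(ctrl, v, method = test_for(m))
            comparisons[[key]] <- list(p_value = cmp$p_value,
                                       method = cmp$method)
          }
        }
      }
    }
    out[[m]] <- list(split_tests = split_tests, comparisons = comparisons)
  }
  out
}

write_provenance <- function(config) {
  cfg_path <- file.path(config$output_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE)
  prov <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("memquant")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(prov, file.path(config$output_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(prov)
}
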