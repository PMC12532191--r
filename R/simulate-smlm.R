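#' Ground truth for a synthetic qSMLM acquisition
#'
#' Describes a field of clustered plus background molecules imaged by
#' single-molecule localization microscopy with fluorophore blinking,
#' localization noise, stage drift and fiducial markers. Defaults emulate a
#' typical dSTORM acquisition of OlyA-AF647-stained membrane: 60,000 frames
#' at 10 ms exposure, mean localizations per probe `alpha_true = 3.3`,
#' nanodomains of ~30 nm Gaussian spread with ~10 molecules each.
#'
#' @param field_size field side length in um (square field).
#' @param n_frames number of camera frames.
#' @param frame_exposure exposure per frame in s.
#' @param cluster_density nanodomain centers per um^2 (homogeneous Poisson);
#'   ignored when `cluster_centers` is supplied.
#' @param cluster_centers optional matrix/data.frame of cluster centers (nm).
#' @param molecules_per_cluster_mean Poisson mean of molecules per cluster.
#' @param cluster_sigma isotropic Gaussian spread of cluster members (nm).
#' @param background_density non-clustered molecules per um^2 (CSR).
#' @param molecule_positions optional explicit molecule positions (nm,
#'   two-column); when supplied, no clusters or background are drawn.
#' @param alpha_true mean localization appearances per molecule (>= 1).
#' @param dark_time_scale mean dark gap between appearances, in s.
#' @param localization_precision per-axis localization noise SD in nm.
#' @param drift_velocity linear stage drift, nm/frame, length-2 (x, y).
#' @param n_fiducials number of fiducial beads (visible in every frame).
#' @return an object of class `smlm_truth` (a validated list).
#' @export
smlm_truth <- function(field_size = 6, n_frames = 60000, frame_exposure = 0.01,
                       cluster_density = 5, cluster_centers = NULL,
                       molecules_per_cluster_mean = 10, cluster_sigma = 30,
                       background_density = 20, molecule_positions = NULL,
                       alpha_true = 3.3, dark_time_scale = 25,
                       localization_precision = 15,
                       drift_velocity = c(100, -50) / n_frames,
                       n_fiducials = 3) {
  check_scalar(field_size, "field_size", 0, strict_lower = TRUE)
  check_scalar(n_frames, "n_frames", 1)
  check_scalar(frame_exposure, "frame_exposure", 0, strict_lower = TRUE)
  check_scalar(cluster_density, "cluster_density", 0)
  check_scalar(molecules_per_cluster_mean, "molecules_per_cluster_mean", 0)
  check_scalar(cluster_sigma, "cluster_sigma", 0)
  check_scalar(background_density, "background_density", 0)
  check_scalar(alpha_true, "alpha_true", 1)
  check_scalar(dark_time_scale, "dark_time_scale", 0, strict_lower = TRUE)
  check_scalar(localization_precision, "localization_precision", 0)
  stopifnot(length(drift_velocity) == 2, is.numeric(drift_velocity))
  check_scalar(n_fiducials, "n_fiducials", 0)
  if (!is.null(cluster_centers)) cluster_centers <- as.matrix(cluster_centers)
  if (!is.null(molecule_positions))
    molecule_positions <- as.matrix(molecule_positions)
  structure(list(
    field_size = field_size, n_frames = as.integer(n_frames),
    frame_exposure = frame_exposure,
    cluster_density = cluster_density, cluster_centers = cluster_centers,
    molecules_per_cluster_mean = molecules_per_cluster_mean,
    cluster_sigma = cluster_sigma, background_density = background_density,
    molecule_positions = molecule_positions,
    alpha_true = alpha_true, dark_time_scale = dark_time_scale,
    localization_precision = localization_precision,
    drift_velocity = as.numeric(drift_velocity),
    n_fiducials = as.integer(n_fiducials)
  ), class = "smlm_truth")
}

#' Simulate a blinking localization table from ground truth
#'
#' Cluster centers follow a homogeneous Poisson process, member counts are
#' Poisson, member positions isotropic Gaussian around the center, background
#' molecules are completely spatially random. Each molecule produces
#' `k = 1 + Geometric` localization appearances (mean `alpha_true`), with
#' successive appearances separated by exponential dark gaps of mean
#' `dark_time_scale`; the burst train start is drawn uniformly over the part
#' of the acquisition where the whole train fits, so no appearance is
#' truncated and the realized appearance count keeps its nominal law. Every
#' localization is displaced by Gaussian localization noise plus the
#' cumulative linear drift at its frame. Fiducial beads are emitted in every
#' frame and flagged in the `is_fiducial` column.
#'
#' @param truth an [smlm_truth()] object.
#' @param seed integer seed (one generator per call; caller RNG untouched).
#' @return list with `localizations` (data.frame `frame, x_nm, y_nm,
#'   precision_nm, is_fiducial`, sorted by frame) and `truth` augmented with
#'   the realized molecule positions, cluster centers and fiducial positions.
#' @export
simulate_smlm <- function(truth, seed) {
  stopifnot(inherits(truth, "smlm_truth"))
  with_seed(seed, {
    L <- truth$field_size * 1000  # nm
    area <- truth$field_size^2    # um^2

    if (!is.null(truth$molecule_positions)) {
      mol <- truth$molecule_positions
      centers <- truth$cluster_centers
    } else {
      centers <- truth$cluster_centers
      if (is.null(centers)) {
        n_c <- rpois(1, truth$cluster_density * area)
        centers <- cbind(runif(n_c, 0, L), runif(n_c, 0, L))
      }
      n_c <- nrow(centers)
      members <- if (n_c > 0) rpois(n_c, truth$molecules_per_cluster_mean)
                 else integer(0)
      n_cl_mol <- sum(members)
      cl <- if (n_cl_mol > 0) {
        cid <- rep(seq_len(n_c), members)
        cbind(centers[cid, 1] + rnorm(n_cl_mol, 0, truth$cluster_sigma),
              centers[cid, 2] + rnorm(n_cl_mol, 0, truth$cluster_sigma))
      } else matrix(numeric(0), ncol = 2)
      n_bg <- rpois(1, truth$background_density * area)
      bg <- cbind(runif(n_bg, 0, L), runif(n_bg, 0, L))
      mol <- rbind(cl, bg)
      # keep molecules inside the field (cluster members can spill over)
      mol[, 1] <- pmin(pmax(mol[, 1], 0), L)
      mol[, 2] <- pmin(pmax(mol[, 2], 0), L)
    }
    n_mol <- nrow(mol)

    exp_total <- n_mol * truth$alpha_true +
      truth$n_fiducials * truth$n_frames
    if (exp_total > 1e7)
      stop("expected localization count ", round(exp_total),
           " exceeds 1e7; reduce field, frames or fiducials")

    # appearances per molecule: 1 + Geometric with mean alpha_true
    k <- if (truth$alpha_true > 1 && n_mol > 0)
      1L + rgeom(n_mol, prob = 1 / truth$alpha_true)
    else rep(1L, n_mol)
    n_loc <- sum(k)
    mol_id <- rep(seq_len(n_mol), k)

    # burst frame offsets: exponential dark gaps (in frames)
    dark_frames <- truth$dark_time_scale / truth$frame_exposure
    gap <- rexp(n_loc, rate = 1 / dark_frames)
    first <- !duplicated(mol_id)
    gap[first] <- 0
    cs <- cumsum(gap)
    first_idx <- which(first)
    offset <- cs - cs[first_idx][mol_id]
    span <- if (n_mol > 0) offset[cumsum(k)] else numeric(0)
    start <- floor(runif(n_mol, 0, pmax(truth$n_frames - span, 1)))
    frames <- pmin(pmax(round(start[mol_id] + offset), 0), truth$n_frames - 1L)

    prec <- truth$localization_precision
    x <- mol[mol_id, 1] + rnorm(n_loc, 0, prec) +
      truth$drift_velocity[1] * frames
    y <- mol[mol_id, 2] + rnorm(n_loc, 0, prec) +
      truth$drift_velocity[2] * frames

    # fiducials: one localization per bead per frame
    n_f <- truth$n_fiducials
    if (n_f > 0) {
      fid_pos <- cbind(runif(n_f, 0.1 * L, 0.9 * L),
                       runif(n_f, 0.1 * L, 0.9 * L))
      ff <- rep(0:(truth$n_frames - 1L), times = n_f)
      fid_id <- rep(seq_len(n_f), each = truth$n_frames)
      fx <- fid_pos[fid_id, 1] + rnorm(length(ff), 0, prec) +
        truth$drift_velocity[1] * ff
      fy <- fid_pos[fid_id, 2] + rnorm(length(ff), 0, prec) +
        truth$drift_velocity[2] * ff
    } else {
      fid_pos <- matrix(numeric(0), ncol = 2)
      ff <- integer(0); fx <- fy <- numeric(0)
    }

    tab <- data.frame(
      frame = c(as.integer(frames), as.integer(ff)),
      x_nm = c(x, fx), y_nm = c(y, fy),
      precision_nm = prec,
      is_fiducial = c(rep(FALSE, n_loc), rep(TRUE, length(ff)))
    )
    tab <- tab[order(tab$frame), , drop = FALSE]
    rownames(tab) <- NULL

    truth$molecule_positions <- mol
    truth$cluster_centers <- centers
    truth$fiducial_positions <- fid_pos
    truth$n_molecules <- n_mol
    list(localizations = tab, truth = truth)
  })
}
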