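#' Density-seeded cluster assignment with blinking-corrected membership
#'
#' A k-means-like algorithm whose cluster count is data driven: seed centers
#' are local maxima of a 2D histogram with bin size `cluster_radius` (seeds
#' closer than `cluster_radius` are merged); each point is then assigned to
#' its nearest center if within `2 * cluster_radius`, centers are recomputed
#' as member centroids, and the loop repeats until assignments are stable or
#' `max_iter` is reached. Clusters with more than four molecules are kept;
#' when the input points are localizations rather than molecules, membership
#' is converted to molecules by dividing localization counts by `alpha`, the
#' blinking correction.
#'
#' @param positions two-column matrix/data.frame of point positions in nm
#'   (molecule positions, or localizations combined with `alpha`).
#' @param cluster_radius cluster radius in nm (typically the
#'   pair-correlation length xi).
#' @param area_um2 reference area in um^2 for per-area rates; defaults to
#'   the bounding-box area of the input.
#' @param alpha localizations per molecule for membership conversion
#'   (1 when `positions` already are molecules).
#' @param min_molecules clusters must exceed this many molecules (default 4:
#'   the more-than-four-molecules rule).
#' @param max_iter assignment iteration cap.
#' @return object of class `cluster_report`: list with `n_clusters`,
#'   `molecules_per_cluster` (mean over kept clusters), `clusters_per_area`
#'   (1/um^2), `clustered_fraction`, `detected_density` (molecules/um^2),
#'   `clusters` (data.frame of centers and sizes), `assignment` (integer
#'   label per input point, 0 = unclustered).
#' @export
assign_clusters <- function(positions, cluster_radius, area_um2 = NULL,
                            alpha = 1, min_molecules = 4, max_iter = 100) {
  check_scalar(cluster_radius, "cluster_radius", 0, strict_lower = TRUE)
  check_scalar(alpha, "alpha", 1)
  pos <- as.matrix(positions)
  n <- nrow(pos)
  empty <- list(n_clusters = 0L, molecules_per_cluster = 0,
                clusters_per_area = 0, clustered_fraction = 0,
                detected_density = 0,
                clusters = data.frame(x_nm = numeric(0), y_nm = numeric(0),
                                      n_points = integer(0),
                                      n_molecules = numeric(0)),
                assignment = integer(0))
  class(empty) <- "cluster_report"
  if (n == 0) return(empty)
  if (is.null(area_um2)) {
    span <- apply(pos, 2, function(v) diff(range(v)))
    area_um2 <- max(prod(span) / 1e6, 1e-6)
  }
  empty$detected_density <- (n / alpha) / area_um2
  empty$assignment <- integer(n)

  centers <- histogram_seeds(pos, cluster_radius)
  if (nrow(centers) == 0) return(empty)

  assign_prev <- rep(-1L, n)
  for (iter in seq_len(max_iter)) {
    d2 <- nearest_center(pos, centers)
    lab <- d2$index
    lab[d2$dist > 2 * cluster_radius] <- 0L
    # recompute centers; drop empty ones
    keep <- sort(unique(lab[lab > 0L]))
    if (length(keep) == 0) { lab <- integer(n); break }
    centers <- t(vapply(keep, function(k)
      colMeans(pos[lab == k, , drop = FALSE]), numeric(2)))
    lab <- match(lab, keep, nomatch = 0L)
    # merge centers that collapsed onto each other
    if (nrow(centers) > 1) {
      ml <- spatial_linkage(centers[, 1], centers[, 2], cluster_radius / 2)
      if (max(ml) < nrow(centers)) {
        centers <- t(vapply(seq_len(max(ml)), function(k)
          colMeans(centers[ml == k, , drop = FALSE]), numeric(2)))
        lab <- ifelse(lab > 0L, ml[lab], 0L)
      }
    }
    if (identical(lab, assign_prev)) break
    assign_prev <- lab
  }

  sizes <- tabulate(lab[lab > 0L], nbins = max(lab, 1L))
  mol_sizes <- sizes / alpha
  kept <- which(mol_sizes > min_molecules)
  if (length(kept) == 0) return(empty)
  relab <- integer(n)
  relab[lab %in% kept] <- match(lab[lab %in% kept], kept)
  clusters <- data.frame(
    x_nm = centers[kept, 1], y_nm = centers[kept, 2],
    n_points = sizes[kept], n_molecules = mol_sizes[kept]
  )
  out <- list(
    n_clusters = length(kept),
    molecules_per_cluster = mean(mol_sizes[kept]),
    clusters_per_area = length(kept) / area_um2,
    clustered_fraction = sum(sizes[kept]) / n,
    detected_density = (n / alpha) / area_um2,
    clusters = clusters, assignment = relab
  )
  class(out) <- "cluster_report"
  out
}

# Seed centers: local maxima (8-neighbourhood, >=) of the 2D count histogram
# with bin size = cluster_radius; seeds closer than cluster_radius are merged
# into their centroid.
histogram_seeds <- function(pos, bin) {
  # anchor the grid at the data minimum so reports are translation invariant
  x0 <- min(pos[, 1]); y0 <- min(pos[, 2])
  gx <- floor((pos[, 1] - x0) / bin); gy <- floor((pos[, 2] - y0) / bin)
  ox <- min(gx); oy <- min(gy)
  gx <- gx - ox + 1L; gy <- gy - oy + 1L
  nx <- max(gx); ny <- max(gy)
  h <- matrix(0L, nx, ny)
  cnt <- table(factor(gx, levels = 1:nx), factor(gy, levels = 1:ny))
  h[] <- as.integer(cnt)
  # pad and compare against the 8-neighbourhood maximum
  hp <- matrix(0L, nx + 2, ny + 2)
  hp[2:(nx + 1), 2:(ny + 1)] <- h
  nbmax <- matrix(0L, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nbmax <- pmax(nbmax, hp[(2:(nx + 1)) + dx, (2:(ny + 1)) + dy])
  }
  is_max <- h > 0L & h >= nbmax
  idx <- which(is_max, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(0), ncol = 2))
  # bin-center coordinates (idx is 1-based within the shifted grid)
  centers <- cbind(x0 + (idx[, 1] + ox - 2L + 0.5) * bin,
                   y0 + (idx[, 2] + oy - 2L + 0.5) * bin)
  if (nrow(centers) > 1) {
    ml <- spatial_linkage(centers[, 1], centers[, 2], bin)
    centers <- t(vapply(seq_len(max(ml)), function(k)
      colMeans(centers[ml == k, , drop = FALSE]), numeric(2)))
  }
  centers
}

# index and distance of the nearest center for each point
nearest_center <- function(pos, centers) {
  nc <- nrow(centers)
  d2 <- matrix(Inf, nrow(pos), nc)
  for (k in seq_len(nc)) {
    d2[, k] <- (pos[, 1] - centers[k, 1])^2 + (pos[, 2] - centers[k, 2])^2
  }
  idx <- max.col(-d2, ties.method = "first")
  list(index = idx, dist = sqrt(d2[cbind(seq_len(nrow(pos)), idx)]))
}
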