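#include <Rcpp.h>
using namespace Rcpp;

// Brownian-dynamics photon trace through a 3D Gaussian observation volume.
//
// Particles take one Brownian step per bin (no sub-stepping): per-axis
// displacement SD = sqrt(2 * D * dt). 3D particles diffuse in a periodic box
// [-box/2, box/2]^2 x [-box_z/2, box_z/2]; 2D particles are confined to the
// focal plane z = 0. Detection weight per particle:
//   w = exp(-2 (x^2 + y^2) / omega_xy^2) * exp(-2 z^2 / omega_z^2).
// A two-state telegraph (triplet) process gates emission with stationary
// dark fraction triplet_fraction and relaxation time triplet_tau.
// Photon counts per bin ~ Poisson(brightness * sum(w_bright) * dt).
// Uses R's RNG, so results are reproducible under set.seed().
// [[Rcpp::export]]
IntegerVector fcs_simulate_counts(int n_bins, double bin_time,
                                  int n2d, int n3d,
                                  double d2d, double d3d,
                                  double box_xy, double box_z,
                                  double omega_xy, double omega_z,
                                  double triplet_fraction, double triplet_tau,
                                  double brightness,
                                  Nullable<NumericMatrix> init2d = R_NilValue,
                                  Nullable<NumericMatrix> init3d = R_NilValue) {
  const int n = n2d + n3d;
  std::vector<double> px(n), py(n), pz(n, 0.0);
  std::vector<int> bright(n, 1);

  // initial positions: uniform in the box unless supplied
  if (init2d.isNotNull()) {
    NumericMatrix m(init2d.get());
    if (m.nrow() != n2d || m.ncol() < 2) stop("init2d must be n2d x 2");
    for (int i = 0; i < n2d; ++i) { px[i] = m(i, 0); py[i] = m(i, 1); }
  } else {
    for (int i = 0; i < n2d; ++i) {
      px[i] = R::runif(-box_xy / 2, box_xy / 2);
      py[i] = R::runif(-box_xy / 2, box_xy / 2);
    }
  }
  if (init3d.isNotNull()) {
    NumericMatrix m(init3d.get());
    if (m.nrow() != n3d || m.ncol() < 3) stop("init3d must be n3d x 3");
    for (int i = 0; i < n3d; ++i) {
      px[n2d + i] = m(i, 0); py[n2d + i] = m(i, 1); pz[n2d + i] = m(i, 2);
    }
  } else {
    for (int i = 0; i < n3d; ++i) {
      px[n2d + i] = R::runif(-box_xy / 2, box_xy / 2);
      py[n2d + i] = R::runif(-box_xy / 2, box_xy / 2);
      pz[n2d + i] = R::runif(-box_z / 2, box_z / 2);
    }
  }

  const double s2d = std::sqrt(2.0 * d2d * bin_time);
  const double s3d = std::sqrt(2.0 * d3d * bin_time);
  const bool triplet = triplet_fraction > 0.0 && triplet_tau > 0.0;
  // telegraph transition probabilities per step (rate * dt, clipped)
  double p_to_dark = 0.0, p_to_bright = 0.0;
  if (triplet) {
    p_to_dark = std::min(1.0, triplet_fraction / triplet_tau * bin_time);
    p_to_bright = std::min(1.0, (1.0 - triplet_fraction) / triplet_tau * bin_time);
    for (int i = 0; i < n; ++i)
      bright[i] = (R::unif_rand() < triplet_fraction) ? 0 : 1;
  }

  const double wxy = 2.0 / (omega_xy * omega_xy);
  const double wz = (omega_z > 0) ? 2.0 / (omega_z * omega_z) : 0.0;
  IntegerVector counts(n_bins);

  auto wrap = [](double v, double half) {
    // periodic wrap into [-half, half)
    const double span = 2.0 * half;
    v += half;
    v -= span * std::floor(v / span);
    return v - half;
  };

  for (int t = 0; t < n_bins; ++t) {
    double wsum = 0.0;
    for (int i = 0; i < n; ++i) {
      const bool is2d = i < n2d;
      const double sd = is2d ? s2d : s3d;
      if (sd > 0) {
        px[i] = wrap(px[i] + R::norm_rand() * sd, box_xy / 2);
        py[i] = wrap(py[i] + R::norm_rand() * sd, box_xy / 2);
        if (!is2d) pz[i] = wrap(pz[i] + R::norm_rand() * sd, box_z / 2);
      }
      if (triplet) {
        if (bright[i]) { if (R::unif_rand() < p_to_dark) bright[i] = 0; }
        else           { if (R::unif_rand() < p_to_bright) bright[i] = 1; }
      }
      if (bright[i]) {
        double w = std::exp(-wxy * (px[i] * px[i] + py[i] * py[i]));
        if (!is2d) w *= std::exp(-wz * pz[i] * pz[i]);
        wsum += w;
      }
    }
    counts[t] = (int) R::rpois(brightness * wsum * bin_time);
  }
  return counts;
}
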