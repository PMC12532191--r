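#!/usr/bin/env Rscript

# Simulates the synthetic study cohorts that the downstream analysis
# scripts consume: a control condition and a "domain-remodeling" treatment
# that widens the Chol/SM nanodomains and raises their occupancy, plus
# matched FCS, calcium-ratio and GP imaging acquisitions per cell.
# Everything is seeded; re-running reproduces the data byte for byte.

suppressPackageStartupMessages(library(memquant))

# bulk per-cell data (localization tables, traces, TIFFs) is reproducible
# from the seed and lives under scratch/; only the small result tables in
# results/ are part of the curated output
out_root <- file.path("scratch", "cohort")
seed <- 20260923L

# qSMLM acquisitions are generated at a reduced frame count so the whole
# cohort simulates in about a minute; the statistical structure (cluster
# geometry, blinking law, drift, fiducials) is the full one.
smlm_ctrl <- list(field_size = 4, n_frames = 5000, cluster_density = 5,
                  molecules_per_cluster_mean = 10, cluster_sigma = 30,
                  background_density = 20, alpha_true = 3.3,
                  dark_time_scale = 2.5, localization_precision = 15,
                  n_fiducials = 3)
smlm_treat <- utils::modifyList(smlm_ctrl,
                                list(cluster_sigma = 45,
                                     molecules_per_cluster_mean = 13))

fcs_ctrl <- list(d_2d = 0.5, n_particles_2d = 540, brightness = 3e4,
                 bin_time = 1e-3, duration = 60, box_size = 6)
fcs_treat <- utils::modifyList(fcs_ctrl, list(d_2d = 0.25))

ratio_ctrl <- list(baseline_ratio = 1.0, amplitude = 0.5, noise_sd = 2)
ratio_treat <- utils::modifyList(ratio_ctrl,
                                 list(baseline_ratio = 1.3,
                                      amplitude = 0.7))

gp_ctrl <- list(gp_true = 0.30, noise_sd = 4)
gp_treat <- utils::modifyList(gp_ctrl, list(gp_true = 0.22))

cfg <- run_config(
  mode = "simulate", seed = seed, output_dir = out_root,
  conditions = list(
    control = list(smlm = smlm_ctrl, fcs = fcs_ctrl,
                   ratio = ratio_ctrl, gp = gp_ctrl),
    treated = list(smlm = smlm_treat, fcs = fcs_treat,
                   ratio = ratio_treat, gp = gp_treat)
  ),
  control = "control", n_cells = 11,
  modules = list(smlm = list(), fcs = list(), ratio = list(), gp = list())
)

run(cfg)

n_files <- length(list.files(file.path(out_root, "data"), recursive = TRUE))
cat("simulated 2 conditions x 11 cells ->", n_files,
    "files under", file.path(out_root, "data"), "\n")
cat("ground truth sits in the per-cell *_truth.json sidecars\n")
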