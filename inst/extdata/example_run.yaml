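# Example end-to-end run configuration: two conditions, qSMLM + GP
# modules, reduced per-cell acquisition scale. Load with
# load_run_config() and execute with run().
mode: full
seed: 101
output_dir: scratch/example_run
control: control
n_cells: 6
conditions:
  control:
    smlm:
      field_size: 4
      n_frames: 5000
      cluster_density: 5
      molecules_per_cluster_mean: 10
      cluster_sigma: 30
      background_density: 20
      alpha_true: 3.3
      dark_time_scale: 2.5
      localization_precision: 15
      n_fiducials: 3
    gp:
      gp_true: 0.30
      noise_sd: 4
  treated:
    smlm:
      field_size: 4
      n_frames: 5000
      cluster_density: 5
      molecules_per_cluster_mean: 13
      cluster_sigma: 45
      background_density: 20
      alpha_true: 3.3
      dark_time_scale: 2.5
      localization_precision: 15
      n_fiducials: 3
    gp:
      gp_true: 0.22
      noise_sd: 4
modules:
  smlm:
    alpha: 3.3
    n_rois: 1
  gp:
    n_profiles: 8
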