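# Reference pipeline configuration: dual-colour clustered scenes in the
# 120 x 120 px (78 nm pixels) analysis field, 4 ms/frame acquisition
# parameters, and the default analysis settings (R_max 500 nm, dR 50 nm,
# TALL radius 50 nm / 32 ms threshold).
seed: 1
out_dir: pipeline_out
roi: {x_min: 0, y_min: 0, x_max: 9360, y_max: 9360}
stages:
  simulate:
    enabled: true
    scene_a:
      n_clusters: 20
      cluster_radius_sd: 45
      locs_per_cluster: 50
      background_locs: 1000
      localization_precision_sd: 22.0   # SF650B
      mean_blink_repeats: 1
    scene_b:
      n_clusters: 20
      cluster_radius_sd: 45
      locs_per_cluster: 50
      background_locs: 1000
      localization_precision_sd: 26.3   # mEos4b
      mean_blink_repeats: 1
    coloc_fraction: 1.0
    trajectories:
      model: brownian
      D: 1.0                  # um^2/s
      frame_interval: 0.004   # s
      n_frames: 50
      n_trajectories: 200
  cluster:
    enabled: true
    n_simulations: 100
  doc:
    enabled: true
    r_max: 500
    dr: 50
    min_total_localizations: 30
    control: true
  track:
    enabled: true
    windows: ["12ms@4ms", "24ms@4ms"]
  tall:
    enabled: true
    detection_radius: 50
    threshold_trapped_period: 0.032
    min_trajectory_length: 10
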