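out_dir: epioct_run
scan_dir: epioct_run/scans
profile_dir: epioct_run/profiles
report_dir: epioct_run/report
n_subjects: 1
seed: 1
meridians:
- horizontal
- vertical
eyes:
- OD
- OS
tests:
- 1
- 2
geometry:
  lateral_width_mm: 13.465
  n_ascans: 512
  axial_depth_air_mm: 7.281
  n_samples: 1024
  axial_psf_fwhm_um: 4.6
cornea:
  anterior_radius_mm: 7.8
  apex_x_mm: 0.0
  apex_z_mm: 1.2
  tilt_deg: 0.0
  central_thickness_um: 52.0
  peripheral_thickness_um:
  - 63.0
  - 63.0
  - 58.0
  - 72.0
  thickness_exponent: 3.0
  peripheral_distance_mm: 5.0
  direction_coeffs:
  - 0.088
  - 0.088
  - 0.048
  - 0.16
  group_index: 1.389
noise:
  background_sd: 0.04
  surface_amplitude: 1.0
  back_reflectivity: 0.6
  speckle_factor: 0.35
  depth_rolloff_mm: 1.8
  seed: 1
population:
  t0_mean_um: 52.0
  t0_sd_um: 3.2
  inter_eye_sd_um: 0.8
  radius_mean_mm: 7.8
  radius_sd_mm: 0.25
  apex_depth_mm: 1.2
  apex_depth_sd_mm: 0.15
  decentration_sd_mm: 0.2
  tilt_sd_deg: 0.5
segmentation:
  smooth_sigma_um: ~
  jump_limit_um: 60.0
  smoothness_penalty: 0.02
  min_separation_um: 20.0
  max_separation_um: 250.0
  snr_threshold: 6.0
  boundary_margin_mm: 0.15
refraction:
  n_air: 1.0
  n_tissue: 1.389
  normal_fit_halfwidth_mm: 0.25
  normal_fit_degree: 2
anchor: apex
design: test_retest
verbosity: 1
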