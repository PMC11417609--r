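# Demonstration run: small dual-phantom imaging study plus a measurement-level
# paired cohort, calibrated and validated end to end. Doubles as the
# integration-test fixture; reruns are byte-identical.
seed: 20260901
phantoms:
- name: plate_demo
  kind: plate_lattice
  extent_mm: [1.2, 1.2, 1.2]
  thickness_um: 200.0
  spacing_um: 600.0
  tissue_density_mgHA: 1200.0
  raster_voxel_um: 20.0
- name: shell_demo
  kind: cortical_shell
  extent_mm: [2.4, 2.4, 0.6]
  wall_um: 400.0
  pore_diameter_um: 160.0
  pore_fraction: 0.06
  tissue_density_mgHA: 1200.0
  raster_voxel_um: 20.0
profiles:
  xcti:
    name: XCTI_like
    noise_sd_mgHA: 25.0
  xctii:
    name: XCTII_like
    noise_sd_mgHA: 25.0
segmentation:
  gaussian:
    sigma_voxels: 0.8
    support_voxels: 1
    threshold_trab_mgHA: 320.0
    threshold_cort_mgHA: 450.0
  lh:
    hamming_cutoff_fraction: 0.8
    threshold_fraction: 0.4
    epsilon_laplace_weight: 0.5
morphometry:
  matrix_density_mgHA: 1200.0
  xcti_indirect: yes
cohort:
  n_subjects: 8
  parameters:
  - parameter: BV/TV
    true_slope: 1.66
    true_intercept: 0.01
    xcti_mean: 0.15
    xcti_sd: 0.04
    noise_sd: 0.01
  - parameter: Tt.BMD
    true_slope: 1.0
    true_intercept: 0.06
    xcti_mean: 300.0
    xcti_sd: 60.0
    noise_sd: 5.0
  - parameter: Ct.Po
    true_slope: 0.47
    true_intercept: 0.0
    xcti_mean: 0.04
    xcti_sd: 0.015
    noise_sd: 0.004
calibration:
  n_boot: 100
  draw_size: 5
  n_test: 3
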