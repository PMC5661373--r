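# Demonstration pipeline configuration: single-voxel acquisition with
# realistic drift, phase jitter, noise and residual water, followed by
# reconstruction and difference-spectrum quantification.
sequence:
  te_ms: 68
  tr_ms: 2000
  larmor_mhz: 297.2
  carrier_ppm: 4.7
  sweep_hz: 4000
  n_points: 1024
  edit_fwhm_hz: 60
scheme: symmetric_1p7
phantom:
  gaba: 0.2
  mm: 0.3
  linewidth_hz: 8
  residual_water_amp: 2
encoding:
  matrix: [1, 1, 1]
  averages: 64
coils:
  n: 8
  seed: 11
noise:
  sd: 0.02
  drift_hz_per_avg: 0.1
  phase_sd_deg: 3
  seed: 7
quant:
  fit_range_ppm: [1.8, 4.1]
  baseline_order: 2
  lw_hz: 8
voxel: [1, 1, 1]
out_dir: gabedit_run
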