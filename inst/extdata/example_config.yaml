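# Example run configuration: a polydisperse liposome-like suspension
# observed at 100 frames/s in a 15 pL detection volume, plus DLS settings.
seed: 1
medium:
  temperature: 298.15        # K (water at 25 C)
  viscosity: 8.9e-4          # Pa s
  refractive_index: 1.33
acquisition:
  frame_interval: 0.01       # s
  n_frames: 200
  detection_volume_pl: 15
  localization_noise_sd_nm: 20
  detection_probability: 0.95
  dilution_factor: 100
dls:
  wavelength_nm: 660
  angle_deg: 90
  beta: 0.9
  noise_sd: 0.002
  lag_min_s: 1.0e-6
  lag_max_s: 1.0
  n_lags: 200
populations:
  - {shape: sphere, rh_nm: 60, number_density_per_ml: 5.0e12}
  - {shape: sphere, rh_nm: 150, number_density_per_ml: 1.0e12}
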