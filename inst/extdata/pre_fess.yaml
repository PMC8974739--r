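# Pre-surgery experiment: 46 frames over 69 s, laminar xenon from 10.5 s,
# pulsation 34.5-52.5 s, room-air washout with pulsation from 63 s.
variant: pre_fess
seed: 42
phantom:
  grid_shape: [64, 64, 48]
  voxel_mm: [3.0, 3.0, 3.0]
  nasal_tau_s: 2.5
  noise_sigma_hu: 5
  e100_hu: {low_kv: 330.0, high_kv: 175.0, mixed: 250.0}
analysis:
  channel: mixed
  enhancement_mode: constant
  input_side: left
  erode_voxels: 0
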