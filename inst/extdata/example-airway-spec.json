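{
  "pharynx_z_range": [0, 80],
  "a": 10,
  "b": 6,
  "c_offset": 0,
  "nasal_radii": [3.5, 3.5],
  "nasal_length": 20,
  "nasal_x_offset": 7,
  "angular_resolution": 64,
  "axial_resolution": 0.5,
  "noise_amp": 0,
  "seed": 1
}
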