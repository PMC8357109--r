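{
  "planes": {
    "top": {
      "z": 60,
      "dy": 0,
      "dx_half": 0,
      "label": "fixed plane (geometry unchanged at and above)"
    },
    "middle": {
      "z": 37,
      "dy": 4.0,
      "dx_half": 1.0,
      "label": "soft-palate-tip level"
    },
    "lower": {
      "z": 16,
      "dy": 6.0,
      "dx_half": 2.0,
      "label": "epiglottis-tip level"
    }
  },
  "spine_fix_margin": 0
}
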