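{
  "comment": "Published false-positive filter operating points for real kidney predictions (LADAF-2020-27 left kidney) at three resolutions; documentation only, not reproduced by the synthetic phantom.",
  "levels": {
    "high": {
      "resolution_um_per_voxel": 2.58,
      "variance_lower": 114770.713,
      "variance_upper": 3069051.733,
      "roundness_min": 0.709,
      "radius_min_um": 62,
      "use_cortex_mask": false
    },
    "intermediate": {
      "resolution_um_per_voxel": 12.1,
      "variance_lower": 179663.370,
      "roundness_min": 0.682,
      "radius_min_um": 62,
      "density_window_W": 128,
      "density_min_count_D": 3,
      "use_cortex_mask": false
    },
    "low": {
      "resolution_um_per_voxel": 25.08,
      "radius_min_um": 62,
      "density_window_W": 64,
      "density_min_count_D": 3,
      "use_cortex_mask": true
    }
  },
  "dice_before_after": {
    "high": [0.734, 0.934],
    "intermediate": [0.475, 0.974],
    "low": [0.786, 0.788]
  }
}
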