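{
  "out_dir": null,
  "images_dir": null,
  "masks_dir": null,
  "cohort_csv": null,
  "simulate": true,
  "cohort_params": {
    "n_amd": 38,
    "n_control": 22,
    "age_mean_by_group": {
      "amd_fellow": 71.7,
      "control": 69.4
    },
    "age_sd_by_group": {
      "amd_fellow": 11.7123866056411,
      "control": 8.44274836768217
    },
    "male_prob_by_group": {
      "amd_fellow": 0.684210526315789,
      "control": 0.5
    },
    "axial_length_mean": 24.1,
    "axial_length_sd": 1.2,
    "ccfa_mean_by_group": {
      "amd_fellow": 58.1,
      "control": 62.9
    },
    "ccfa_sd_by_group": {
      "amd_fellow": 6.16441400296898,
      "control": 6.5665820637528
    },
    "cv_mean_by_group": {
      "amd_fellow": 0.182,
      "control": 0.152
    },
    "cv_sd_by_group": {
      "amd_fellow": 0.0431508980207828,
      "control": 0.0286115361349229
    },
    "age_slope_ccfa": -0.2,
    "age_slope_cv": 0.002,
    "faf_prob_by_group": {
      "amd_fellow": 0.236842105263158,
      "control": 0
    },
    "asym_prob_by_group": {
      "amd_fellow": 0.473684210526316,
      "control": 0.318181818181818
    },
    "faf_region_ccfa_offset": -5.1,
    "faf_coverage": 0.15,
    "thin_side_ccfa_offset": -1.7,
    "thin_side_cv_offset": 0.017,
    "region_ccfa_noise_sd": 1.5,
    "region_cv_noise_sd": 0.012,
    "rpe_vol_mean_by_side": {
      "thicker": 0.022,
      "thinner": 0.02
    },
    "rpe_vol_sd": 0.003,
    "seed": null
  },
  "image_params": {
    "width_px": 540,
    "height_px": 540,
    "pixel_scale": 0.005,
    "true_flow_fraction": 0.581,
    "tile_sd": 0.02,
    "texture_corr_len": 2,
    "flow_intensity_mean": 0.75,
    "flow_intensity_sd": 0.08,
    "bg_intensity_mean": 0.35,
    "bg_intensity_sd": 0.08,
    "tile_order": 18,
    "seed": null
  },
  "correct_magnification": false,
  "reference_axial_length": 24.46,
  "target_field_mm": 2.7,
  "phansalkar": {
    "radius_px": 15,
    "k": 0.25,
    "r": 0.5,
    "p_amp": 2,
    "q_decay": 10
  },
  "tile_order": 18,
  "risk_cutoffs": {
    "ccfa": 58.5,
    "cv": 0.165
  },
  "exact_threshold_mw": 20,
  "exact_threshold_wsr": 15,
  "seed": 11
}
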