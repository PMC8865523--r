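{
  "comment": "Illustrative placeholder dose-response coefficients. ERRs per Gy, anthracycline rate-ratio bands (mg/m2, doxorubicin-equivalent) and current-smoker rate ratios are order-of-magnitude values chosen for testing and documentation; substitute coefficients from the primary dose-response literature for any substantive analysis. other_cardiac ships with ERR 0 (background-only) because no published dose-response is available for that group.",
  "endpoints": {
    "coronary_heart_disease": {
      "dose_metric": "whole_heart",
      "err_per_gy": 0.074,
      "chemo_rr": [{"dose_lo": 0, "rr": 1.3}],
      "smoking_rr": 2.2
    },
    "heart_failure": {
      "dose_metric": "left_ventricle",
      "err_per_gy": 0.10,
      "chemo_rr": [
        {"dose_lo": 0, "dose_hi": 250, "rr": 1.7},
        {"dose_lo": 250, "rr": 2.6}
      ],
      "smoking_rr": 1.6
    },
    "valvular_heart_disease": {
      "dose_metric": "sum_valve",
      "err_per_gy": 0.05,
      "age_modifiers": [
        {"age_lo": 0, "age_hi": 25, "err_per_gy": 0.08}
      ],
      "chemo_rr": [{"dose_lo": 0, "rr": 1.4}],
      "smoking_rr": 1.2
    },
    "other_cardiac": {
      "dose_metric": "whole_heart",
      "err_per_gy": 0.0,
      "chemo_rr": [{"dose_lo": 0, "rr": 1.3}],
      "smoking_rr": 1.5
    },
    "stroke": {
      "dose_metric": "carotid_arteries",
      "err_per_gy": 0.05,
      "chemo_rr": [{"dose_lo": 0, "rr": 1.0}],
      "smoking_rr": 1.9
    },
    "lung_cancer": {
      "dose_metric": "lungs",
      "err_per_gy": 0.10,
      "smoking_rr": 14.0
    },
    "breast_cancer": {
      "dose_metric": "breast",
      "err_per_gy": 0.05,
      "age_modifiers": [
        {"age_lo": 0, "age_hi": 25, "err_per_gy": 0.30},
        {"age_lo": 25, "age_hi": 35, "err_per_gy": 0.15}
      ],
      "smoking_rr": 1.0
    },
    "esophageal_cancer": {
      "dose_metric": "esophagus",
      "err_per_gy": 0.10,
      "smoking_rr": 2.0
    }
  }
}
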