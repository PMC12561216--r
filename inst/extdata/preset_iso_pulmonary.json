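{
  "settings": {
    "cardiac_output_target": 5,
    "heart_rate": 70,
    "systolic_fraction": 35,
    "map_target": 20,
    "tpg_target": 2,
    "pa_end_diastolic": 12,
    "peak_systolic_rv": 35,
    "sampling_rate": 1000,
    "n_cycles": 10
  },
  "groups": [
    {
      "label": "G0",
      "rf_mean": 18.54,
      "rf_sd": 8.05,
      "tpg_mean": 1.49,
      "tpg_sd": 0.64,
      "eoa_mean": 3.79,
      "eoa_sd": 0.26
    },
    {
      "label": "G1",
      "rf_mean": 11.19,
      "rf_sd": 6.75,
      "tpg_mean": 1.89,
      "tpg_sd": 0.19,
      "eoa_mean": 3.67,
      "eoa_sd": 0.33
    },
    {
      "label": "G2",
      "rf_mean": 10.41,
      "rf_sd": 2.62,
      "tpg_mean": 1.64,
      "tpg_sd": 0.76,
      "eoa_mean": 3.56,
      "eoa_sd": 0.44
    },
    {
      "label": "G3",
      "rf_mean": 10.1,
      "rf_sd": 2.51,
      "tpg_mean": 1.25,
      "tpg_sd": 0.29,
      "eoa_mean": 3.58,
      "eoa_sd": 0.55
    },
    {
      "label": "G4",
      "rf_mean": 9.66,
      "rf_sd": 2.55,
      "tpg_mean": 1.98,
      "tpg_sd": 0.23,
      "eoa_mean": 3.64,
      "eoa_sd": 0.23
    },
    {
      "label": "G5",
      "rf_mean": 9.22,
      "rf_sd": 1.28,
      "tpg_mean": 2,
      "tpg_sd": 0.24,
      "eoa_mean": 3.61,
      "eoa_sd": 0.17
    },
    {
      "label": "G6",
      "rf_mean": 8.22,
      "rf_sd": 1.27,
      "tpg_mean": 3.06,
      "tpg_sd": 1,
      "eoa_mean": 3.26,
      "eoa_sd": 0.71
    }
  ]
}
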