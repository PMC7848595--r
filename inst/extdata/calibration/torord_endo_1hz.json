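{
  "variant": "torord",
  "celltype": "endo",
  "cl": 1000,
  "par": {
    "n_tm": 2.25848646931447,
    "k_tm": 0.0386195753842252
  },
  "cost": 0,
  "converged": true,
  "achieved": {
    "amplitude": 23.7416077230394,
    "tp": 148.5,
    "rt50": 107.217735266069,
    "rt95": 255.360134765637
  },
  "targets": [
    {
      "biomarker": "amplitude",
      "lower": 10.1,
      "upper": 25.6,
      "weight": 1
    },
    {
      "biomarker": "tp",
      "lower": 137,
      "upper": 179,
      "weight": 1
    },
    {
      "biomarker": "rt50",
      "lower": 101,
      "upper": 133,
      "weight": 1
    },
    {
      "biomarker": "rt95",
      "lower": 248,
      "upper": 539,
      "weight": 1
    }
  ],
  "evaluations": 11,
  "note": "recovered by running calibrate_land() from the uncalibrated steady state; defaults in make_mech_params(calibrated=TRUE) mirror these values"
}
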