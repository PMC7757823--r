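{
  "order": ["height", "sBP", "LDL", "HDL", "BMI", "TG", "GPT", "fBG", "gGT", "HbA1c", "GOT"],
  "b_matrix": [
    [0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
    [-0.03, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0],
    [0.025, 0.045, 0, 0, 0, 0, 0, 0, 0, 0, 0],
    [-0.008, -0.03, -0.019, 0, 0, 0, 0, 0, 0, 0, 0],
    [-0.126, 0.151, -0.015, -0.291, 0, 0, 0, 0, 0, 0, 0],
    [0.02, 0.054, 0.085, -0.421, 0.107, 0, 0, 0, 0, 0, 0],
    [0.027, 0.006, -0.06, 0.02, 0.175, 0.098, 0, 0, 0, 0, 0],
    [0.028, 0.066, -0.038, -0.031, 0.14, 0.089, 0.109, 0, 0, 0, 0],
    [-0.002, 0.008, -0.018, 0.061, 0.016, 0.107, 0.381, 0.046, 0, 0, 0],
    [-0.014, -0.028, -0.002, -0.044, 0.033, 0.012, 0.041, 0.687, -0.021, 0, 0],
    [-0.037, 0.009, -0.026, 0.022, -0.089, -0.036, 0.801, -0.031, 0.064, -0.043, 0]
  ],
  "noise": {
    "height": "laplace",
    "sBP": "laplace",
    "LDL": "laplace",
    "HDL": "laplace",
    "BMI": "laplace",
    "TG": "laplace",
    "GPT": "laplace",
    "fBG": "laplace",
    "gGT": "laplace",
    "HbA1c": "laplace",
    "GOT": "laplace"
  },
  "marginals": [
    {
      "index": "BMI",
      "mean": 22.82,
      "sd": 3.35
    },
    {
      "index": "GOT",
      "mean": 24.33,
      "sd": 9.32
    },
    {
      "index": "GPT",
      "mean": 20.29,
      "sd": 12.18
    },
    {
      "index": "HDL",
      "mean": 63.74,
      "sd": 16.65
    },
    {
      "index": "HbA1c",
      "mean": 5.72,
      "sd": 0.63
    },
    {
      "index": "LDL",
      "mean": 122.67,
      "sd": 30.51
    },
    {
      "index": "TG",
      "mean": 110.45,
      "sd": 66.37
    },
    {
      "index": "fBG",
      "mean": 98.53,
      "sd": 19.28
    },
    {
      "index": "height",
      "mean": 157.87,
      "sd": 9.17
    },
    {
      "index": "sBP",
      "mean": 129.64,
      "sd": 17.49
    },
    {
      "index": "gGT",
      "mean": 33.97,
      "sd": 40.7
    }
  ],
  "n": 131036,
  "missing_rate": 0,
  "outlier_rate": 0,
  "seed": 1
}
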