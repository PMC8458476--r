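{
  "version": "synthetic-1.0",
  "provenance": "SYNTHETIC stand-in coefficient set for testing and demonstration. These are NOT the published PREMM5 model coefficients; they reproduce only the published model's structure (logistic link, positive cancer-history effects, younger diagnosis ages more informative, counts capped at 2). Transcribe the published coefficients into this schema for clinical use.",
  "intercept": -4.3,
  "terms": [
    {"feature": "proband_sex_male",    "transform": {"type": "identity"},                          "coefficient": 0.30},
    {"feature": "proband_crc_count",   "transform": {"type": "count_capped", "cap": 2},            "coefficient": 0.90},
    {"feature": "proband_crc_min_age", "transform": {"type": "youth", "center": 45, "scale": 10},  "coefficient": 0.45},
    {"feature": "proband_ec",          "transform": {"type": "identity"},                          "coefficient": 1.00},
    {"feature": "proband_other_ls",    "transform": {"type": "identity"},                          "coefficient": 0.40},
    {"feature": "fdr_crc_count",       "transform": {"type": "count_capped", "cap": 2},            "coefficient": 0.60},
    {"feature": "fdr_crc_min_age",     "transform": {"type": "youth", "center": 45, "scale": 10},  "coefficient": 0.35},
    {"feature": "sdr_crc_count",       "transform": {"type": "count_capped", "cap": 2},            "coefficient": 0.35},
    {"feature": "sdr_crc_min_age",     "transform": {"type": "youth", "center": 45, "scale": 10},  "coefficient": 0.20},
    {"feature": "fdr_ec",              "transform": {"type": "identity"},                          "coefficient": 0.55},
    {"feature": "sdr_ec",              "transform": {"type": "identity"},                          "coefficient": 0.30},
    {"feature": "fdr_sdr_other_ls",    "transform": {"type": "identity"},                          "coefficient": 0.25},
    {"feature": "ec_min_age",          "transform": {"type": "youth", "center": 45, "scale": 10},  "coefficient": 0.15},
    {"feature": "proband_age",         "transform": {"type": "centered_decade", "center": 45},     "coefficient": -0.10}
  ],
  "absent_age_policy": {"mode": "reference_age", "value": 45}
}
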