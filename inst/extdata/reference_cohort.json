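{
  "description": "Reference cohort parameters for adult mouse lumbar spinal Shox2/Chx10 interneurons: published group compositions and per-subgroup feature distributions (mean, sd) of the 12 measured electrophysiological properties. Used to parameterize the synthetic feature-table generator.",
  "cohort": {"n_total": 171, "n_shox2": 143, "n_chx10": 28},
  "features": {
    "em_mv": "resting membrane potential (mV)",
    "rin_mohm": "input resistance (MOhm)",
    "tau_ms": "membrane time constant (ms)",
    "cm_pf": "membrane capacitance (pF)",
    "rheobase_pa": "rheobase (pA)",
    "ap_threshold_mv": "AP voltage threshold (mV)",
    "ap_halfwidth_ms": "AP half width (ms)",
    "fahp_duration_ms": "fast AHP duration (ms)",
    "sahp_duration_ms": "slow AHP duration (ms)",
    "fahp_amplitude_norm": "fast AHP amplitude, normalized by AP amplitude",
    "pic_on_mv": "persistent inward current onset voltage (mV)",
    "fi_slope_hz_per_pa": "frequency-current slope (Hz/pA)"
  },
  "retained_features": ["em_mv", "cm_pf", "fahp_duration_ms", "fahp_amplitude_norm", "pic_on_mv", "fi_slope_hz_per_pa"],
  "firing_type_counts": {
    "Shox2": {"tonic": 78, "initial_doublet": 36, "initial_burst": 21, "delayed": 8},
    "Chx10": {"tonic": 10, "initial_doublet": 13, "initial_burst": 3, "delayed": 2}
  },
  "kmeans_cluster_counts": {
    "Shox2": {"k1": 23, "k2": 7, "k3": 56, "k4": 57},
    "Chx10": {"k1": 0, "k2": 4, "k3": 12, "k4": 12}
  },
  "hierarchical_cluster_counts": {
    "Shox2": {"H1": 15, "H2": 20, "H3": 24, "H4": 20, "H5": 25, "H6": 39},
    "Chx10": {"H1": 0, "H2": 0, "H3": 8, "H4": 5, "H5": 2, "H6": 13}
  },
  "cluster_specs": [
    {
      "cluster": "k1", "population": "Shox2", "n": 23,
      "mean": {"em_mv": -48.8, "rin_mohm": 408, "tau_ms": 56.9, "cm_pf": 148.3, "rheobase_pa": 21.9, "ap_threshold_mv": -33.4, "ap_halfwidth_ms": 1.01, "fahp_duration_ms": 4.1, "sahp_duration_ms": 62.9, "fahp_amplitude_norm": 0.32, "pic_on_mv": -45.2, "fi_slope_hz_per_pa": 0.36},
      "sd":   {"em_mv": 5, "rin_mohm": 160, "tau_ms": 24, "cm_pf": 67, "rheobase_pa": 14, "ap_threshold_mv": 4, "ap_halfwidth_ms": 0.3, "fahp_duration_ms": 1.2, "sahp_duration_ms": 46, "fahp_amplitude_norm": 0.08, "pic_on_mv": 5, "fi_slope_hz_per_pa": 0.19}
    },
    {
      "cluster": "k2", "population": "Shox2", "n": 7,
      "mean": {"em_mv": -47.3, "rin_mohm": 993, "tau_ms": 47.9, "cm_pf": 53.1, "rheobase_pa": 16.9, "ap_threshold_mv": -32.6, "ap_halfwidth_ms": 1.71, "fahp_duration_ms": 10.2, "sahp_duration_ms": 120.1, "fahp_amplitude_norm": 0.32, "pic_on_mv": -46.4, "fi_slope_hz_per_pa": 0.32},
      "sd":   {"em_mv": 5, "rin_mohm": 388, "tau_ms": 11, "cm_pf": 16, "rheobase_pa": 4, "ap_threshold_mv": 6, "ap_halfwidth_ms": 0.2, "fahp_duration_ms": 2.0, "sahp_duration_ms": 107, "fahp_amplitude_norm": 0.13, "pic_on_mv": 7, "fi_slope_hz_per_pa": 0.12}
    },
    {
      "cluster": "k2", "population": "Chx10", "n": 4,
      "mean": {"em_mv": -44.3, "rin_mohm": 1190, "tau_ms": 35.5, "cm_pf": 30.4, "rheobase_pa": 16.8, "ap_threshold_mv": -38.5, "ap_halfwidth_ms": 1.35, "fahp_duration_ms": 10.5, "sahp_duration_ms": 60.0, "fahp_amplitude_norm": 0.32, "pic_on_mv": -52.1, "fi_slope_hz_per_pa": 0.24},
      "sd":   {"em_mv": 3, "rin_mohm": 567, "tau_ms": 14, "cm_pf": 8, "rheobase_pa": 12, "ap_threshold_mv": 2, "ap_halfwidth_ms": 0.4, "fahp_duration_ms": 3.1, "sahp_duration_ms": 48, "fahp_amplitude_norm": 0.04, "pic_on_mv": 3, "fi_slope_hz_per_pa": 0.21}
    },
    {
      "cluster": "k3", "population": "Shox2", "n": 56,
      "mean": {"em_mv": -44.4, "rin_mohm": 797, "tau_ms": 37.9, "cm_pf": 51.6, "rheobase_pa": 25.1, "ap_threshold_mv": -36.6, "ap_halfwidth_ms": 1.14, "fahp_duration_ms": 4.5, "sahp_duration_ms": 93.6, "fahp_amplitude_norm": 0.23, "pic_on_mv": -47.5, "fi_slope_hz_per_pa": 0.31},
      "sd":   {"em_mv": 3, "rin_mohm": 407, "tau_ms": 18, "cm_pf": 20, "rheobase_pa": 15, "ap_threshold_mv": 2, "ap_halfwidth_ms": 0.3, "fahp_duration_ms": 1.7, "sahp_duration_ms": 64, "fahp_amplitude_norm": 0.07, "pic_on_mv": 4, "fi_slope_hz_per_pa": 0.23}
    },
    {
      "cluster": "k3", "population": "Chx10", "n": 12,
      "mean": {"em_mv": -45.3, "rin_mohm": 770, "tau_ms": 37.9, "cm_pf": 52.9, "rheobase_pa": 25.8, "ap_threshold_mv": -36.7, "ap_halfwidth_ms": 1.20, "fahp_duration_ms": 4.8, "sahp_duration_ms": 72.2, "fahp_amplitude_norm": 0.24, "pic_on_mv": -49.0, "fi_slope_hz_per_pa": 0.19},
      "sd":   {"em_mv": 4, "rin_mohm": 301, "tau_ms": 14, "cm_pf": 19, "rheobase_pa": 15, "ap_threshold_mv": 5, "ap_halfwidth_ms": 0.2, "fahp_duration_ms": 1.0, "sahp_duration_ms": 63, "fahp_amplitude_norm": 0.05, "pic_on_mv": 6, "fi_slope_hz_per_pa": 0.11}
    },
    {
      "cluster": "k4", "population": "Shox2", "n": 57,
      "mean": {"em_mv": -51.7, "rin_mohm": 716, "tau_ms": 37.9, "cm_pf": 56.5, "rheobase_pa": 22.9, "ap_threshold_mv": -37.5, "ap_halfwidth_ms": 1.00, "fahp_duration_ms": 4.1, "sahp_duration_ms": 76.3, "fahp_amplitude_norm": 0.31, "pic_on_mv": -49.5, "fi_slope_hz_per_pa": 0.31},
      "sd":   {"em_mv": 5, "rin_mohm": 321, "tau_ms": 18, "cm_pf": 21, "rheobase_pa": 11, "ap_threshold_mv": 5, "ap_halfwidth_ms": 0.3, "fahp_duration_ms": 1.3, "sahp_duration_ms": 64, "fahp_amplitude_norm": 0.06, "pic_on_mv": 5, "fi_slope_hz_per_pa": 0.17}
    },
    {
      "cluster": "k4", "population": "Chx10", "n": 12,
      "mean": {"em_mv": -52.3, "rin_mohm": 825, "tau_ms": 43.1, "cm_pf": 55.1, "rheobase_pa": 17.0, "ap_threshold_mv": -34.3, "ap_halfwidth_ms": 1.20, "fahp_duration_ms": 4.7, "sahp_duration_ms": 76.9, "fahp_amplitude_norm": 0.26, "pic_on_mv": -50.8, "fi_slope_hz_per_pa": 0.29},
      "sd":   {"em_mv": 5, "rin_mohm": 226, "tau_ms": 15, "cm_pf": 20, "rheobase_pa": 8, "ap_threshold_mv": 4, "ap_halfwidth_ms": 0.3, "fahp_duration_ms": 1.1, "sahp_duration_ms": 42, "fahp_amplitude_norm": 0.07, "pic_on_mv": 4, "fi_slope_hz_per_pa": 0.10}
    }
  ]
}
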