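{
  "synthetic": {
    "n_total": 585,
    "allocation": [2, 1],
    "censor_time": 30,
    "seed": 20230831,
    "medians": {
      "active": { "pfs": 5.7, "os": 15.4 },
      "control": { "pfs": 4.3, "os": 10.9 }
    },
    "shapes": { "pfs": 1.2, "os": 1.0 }
  },
  "analysis": {
    "wtp": 37423,
    "psa_n": 1000,
    "psa_seed": 20230831,
    "scenario_discounts": [0.2, 0.5, 0.8165]
  }
}
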