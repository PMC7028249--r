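{
  "seed": 20260901,
  "n_countries": 18,
  "years": [1970.5, 2030.5],
  "surveys": {
    "MWRA": {
      "n_obs": 77,
      "n_prevalence_obs": 77,
      "n_unmet_obs": 62,
      "n_countries": 18
    },
    "UWRA": {
      "n_obs": 58,
      "n_prevalence_obs": 58,
      "n_unmet_obs": 44,
      "n_countries": 18
    }
  },
  "checksums": {
    "observations_mwra.csv": "f817a52fd375938f7fb6a80ce8f641ea",
    "observations_uwra.csv": "805bf173580aefdf9b065c5ec2980bb6",
    "countries.csv": "003177a7b62765d15b4978ba14bd853e",
    "populations.csv": "593daf30bd363a2e7a0b0a75e39ffe89",
    "truth_params_mwra.csv": "49379c9b03b9811eedeeb37ccbbecd16",
    "truth_params_uwra.csv": "54c7a1fd174d9da1e5d2a40b335bbd6c"
  }
}
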