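{
  "patients": [
    {
      "label": "synthetic-patient-1",
      "file": "patient-01.json",
      "seed": 1,
      "sigma": -0.563383427800269,
      "omega": 30.2372445179728,
      "x_star": [0.419950293483164, 0.761603551637558],
      "grid": {
        "e_min": 0.368,
        "e_max": 0.486,
        "i_min": 0.717,
        "i_max": 0.813,
        "de": 0.001,
        "di": 0.001
      }
    },
    {
      "label": "synthetic-patient-2",
      "file": "patient-02.json",
      "seed": 2,
      "sigma": -2.12905479990035,
      "omega": 29.8319720123347,
      "x_star": [0.887733025115202, 0.867808132219935],
      "grid": {
        "e_min": 0.827,
        "e_max": 0.926,
        "i_min": 0.823,
        "i_max": 0.89,
        "de": 0.001,
        "di": 0.001
      }
    },
    {
      "label": "synthetic-patient-3",
      "file": "patient-03.json",
      "seed": 3,
      "sigma": -1.24969629009337,
      "omega": 29.7473212524622,
      "x_star": [0.805614777830586, 0.60396616366229],
      "grid": {
        "e_min": 0.734,
        "e_max": 0.856,
        "i_min": 0.55,
        "i_max": 0.639,
        "de": 0.001,
        "di": 0.001
      }
    }
  ]
}
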