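{
  "nu": 0.0374868534427548,
  "beta": 3.61353687662631,
  "eta_E": 0.832601136527956,
  "eta_I": 0.122461060527712,
  "w_EE": 3.36875456850976,
  "w_IE": 3.5648763505742,
  "w_EI": 1.23424641927704,
  "zeta": 0.017006510917968,
  "dE0": 0.00279123486580101,
  "label": "synthetic-patient-3"
}
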