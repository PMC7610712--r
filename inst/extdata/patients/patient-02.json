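{
  "nu": 0.0262125057093011,
  "beta": 5.56574115622789,
  "eta_E": 1.26845779875293,
  "eta_I": 0.218127043917775,
  "w_EE": 3.40434036310762,
  "w_IE": 3.36374110076576,
  "w_EI": 1.26159779028967,
  "zeta": 0.0127682801729807,
  "dE0": 0.00198292871586032,
  "label": "synthetic-patient-2"
}
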