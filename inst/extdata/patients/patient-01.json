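{
  "nu": 0.0321398150086303,
  "beta": 2.85920562315732,
  "eta_E": 1.54051135899499,
  "eta_I": 0.487460684962571,
  "w_EE": 2.8195879929699,
  "w_IE": 2.41274966765195,
  "w_EI": 2.18780158879235,
  "zeta": 0.00822898168699761,
  "dE0": 0.00271862349961817,
  "label": "synthetic-patient-1"
}
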