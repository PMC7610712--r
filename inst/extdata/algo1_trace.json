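{
  "comment": "3x3 pencil-and-paper trace of the response-field augmentation rule; synthetic hand-built scenario (bins column-major, u = 4 steps, null = trajectory left the grid)",
  "n_E": 3,
  "n_I": 3,
  "u": 4,
  "gamma0": [0.5, -0.3, 0.1, -1.0, 0.0, -0.5, 0.2, -2.0, 1.0],
  "p_idx": [1, 2, 3, 1, 2, 3, 1, 2, 3,
            2, 3, 3, 2, 2, 2, 1, 2, null,
            2, 2, null, 3, 2, 1, 2, 2, 3,
            2, 1, 2, 3, 2, 1, 3, 1, 2],
  "q_idx": [1, 1, 1, 2, 2, 2, 3, 3, 3,
            1, 2, 2, 2, 2, 3, 2, 2, null,
            2, 3, null, 2, 3, 2, 3, 1, 2,
            3, 2, 2, 3, 3, 1, 3, 1, 3],
  "expected": [0, -0.3, 0, -1.0, 0, -0.5, 0, -2.0, 0,
               -0.3, -0.5, -0.5, 0, 0, -2.0, -1.0, 0, 0,
               0, -2.0, 0, 0, -2.0, -1.0, -2.0, 0, -0.5,
               -2.0, -1.0, 0, 0, -2.0, 0, 0, 0, -2.0]
}
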