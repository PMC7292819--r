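{
  "description": "Per-threshold Binary Switch Model parameter estimates minimising the combined least-squares error against the three U87 glioblastoma monolayer growth curves of Neufeld et al. (2017); densities are fractions of maximum packing density, rates are per hour.",
  "version": 1,
  "fits": [
    {"M": 0, "r": 0.0113, "R": 0.0262, "alpha": 0.174, "beta": 2.82e-6,
     "C0_1": 0.0250, "C0_2": 0.0661, "C0_3": 0.184, "sse": 0.0179},
    {"M": 1, "r": 0.0168, "R": 0.0345, "alpha": 0.0608, "beta": 0.0692,
     "C0_1": 0.0192, "C0_2": 0.0652, "C0_3": 0.188, "sse": 0.0154},
    {"M": 2, "r": 0.0180, "R": 0.0576, "alpha": 2.84e-5, "beta": 0.139,
     "C0_1": 0.0160, "C0_2": 0.0619, "C0_3": 0.191, "sse": 0.0169},
    {"M": 3, "r": 0.0206, "R": 0.0642, "alpha": 3.66e-9, "beta": 0.0892,
     "C0_1": 0.0126, "C0_2": 0.0534, "C0_3": 0.193, "sse": 0.0268},
    {"M": 4, "r": 0.0218, "R": 0.134, "alpha": 3.43e-9, "beta": 0.0623,
     "C0_1": 0.0112, "C0_2": 0.0489, "C0_3": 0.191, "sse": 0.0366},
    {"M": 5, "r": 0.0237, "R": 0.0110, "alpha": 3.73e-10, "beta": 2.34e-4,
     "C0_1": 0.00933, "C0_2": 0.0420, "C0_3": 0.183, "sse": 0.0571}
  ]
}
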