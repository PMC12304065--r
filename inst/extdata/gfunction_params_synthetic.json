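{
  "note": "SYNTHETIC stand-in parameter set for the G-function adaptive-therapy example. The originating study does not print the parameter values of the cited adaptive-dynamics model; these values were calibrated once (see the package vignette) so that the homogeneous model yields long-term tumour control (time-to-progression ~980 days) while the heterogeneous Gaussian-closure variant progresses roughly 25x earlier, the qualitative regime the example illustrates. They are NOT the original study's values.",
  "units": "rates per day; kappa in cells; alpha in trait^2/day",
  "r_max": 0.75,
  "g": 0.1,
  "d": 0.01,
  "k_half": 1,
  "b_res": 60,
  "kappa": 10000,
  "alpha": 1e-05
}
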