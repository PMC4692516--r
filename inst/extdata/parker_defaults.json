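{
  "_comment": "Extended Parker VIF defaults. First-pass Gaussians and sigmoid: Parker et al. population values. Bi-exponential washout (alpha_n, beta_n): synthetic stand-in with redistribution/clearance half-lives of 2 and 40 min, amplitudes anchored to two-compartment gadoterate pharmacokinetics at 0.1 mmol/kg (whole-blood ~1.1 mM at 2 min, ~0.33 mM at 24 min).",
  "A1": 0.809, "A2": 0.330,
  "T1g": 0.17046, "T2g": 0.365,
  "sigma1": 0.0563, "sigma2": 0.132,
  "alpha1": 1.2346, "alpha2": 0.4997,
  "beta1": 0.3465736, "beta2": 0.0173287,
  "s": 38.078, "tau": 0.483,
  "Hct": 0.45
}
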