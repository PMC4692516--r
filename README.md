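# dcebbb

Tracer kinetic modelling of **subtle blood–brain barrier (BBB) leakage**
from low-temporal-resolution DCE-MRI.

In cerebral small vessel disease, lacunar stroke and some dementias the BBB
leaks, but barely: the volume transfer constant is of order
K<sup>Trans</sup> ~ 10⁻⁴ min⁻¹, three orders of magnitude below tumour
values, and the contrast-induced signal change over a 24-minute scan is a
few percent. `dcebbb` implements the quantitative chain appropriate for this
regime — ROI-level curves from a 20-frame, 73 s-resolution SPGR protocol at
1.5 T — and the Monte-Carlo machinery needed to establish when the estimates
can be trusted:

* **Signal model** — SPGR forward signal, enhancement
  E = (S − S₀)/S₀, baseline T1 from the 2°/12° variable-flip-angle pair,
  inversion-recovery T1 fitting, and numerical inversion of the
  enhancement–concentration relation (including the e^(−r₂·C·TE) term, with
  signed, unclipped concentrations).
* **Vascular input function** — extended Parker form: Parker's population
  first-pass Gaussians and sigmoid plus a *bi-exponential* washout
  (redistribution/clearance half-lives 2/40 min) so the tail matches
  gadoterate pharmacokinetics over a 24-minute window; haematocrit
  correction C_p = C_b/(1 − Hct); the highest-peak/noise-score VIF voxel
  tie-break rule.
* **Kinetic models** — nested set: steady-state C_t = v_p C_p, Patlak
  C_t = v_p C_p + K^Trans ∫C_p dτ, modified Tofts (adds back-flux through
  v_e), and the two-compartment exchange model (2CXM) used as the
  generating truth in simulation.
* **Fitting** — the study protocol: constrained multi-start least squares
  (25 restarts, parameters ≥ 0, v_p + v_e ≤ 1, first three post-contrast
  frames excluded from the residuals), exact linear-least-squares start for
  the Patlak model, seed-deterministic.
* **Model selection** — AICc with N = 17 residual points and Akaike
  weights; explicit convention switch for the AIC additive constant.
* **Semi-quantitative arm** — normalised area under the enhancement curve
  and late slope.
* **Simulation engine** — fine-grid (0.1 s) VIF + 2CXM tissue curves,
  frame-window-averaged down-sampling to the 73 s grid, one-shot noise
  calibration to a target concentration CNR, linear scanner drift injected
  in the signal-enhancement domain on both tissue and VIF, and replicate
  experiment drivers for bias and model-selection studies.

The methods vignette (`vignettes/methods.Rmd`) documents the models, the
numerical choices and the simulation design in detail.

## Worked example

Simulate a normal-appearing-white-matter-like acquisition (F_p = 10
ml/100 g/min, PS = 3×10⁻⁴ min⁻¹, v_p = 0.006, v_e = 0.2, T10 = 969 ms,
CNR = 8), fit the nested models and rank them:

```r
library(dcebbb)

cfg  <- sim_config(target_cnr = 8, seed = 42)   # study defaults
pair <- simulate_clean_pair(cfg)                # coarse-grid VIF + tissue
Ct   <- add_noise_to_cnr(pair$Ct, cfg$target_cnr, seed = 42)

fits <- fit_nested_models(Ct, pair$Cp, cfg = fit_config(seed = 1))
fits$patlak
#> <dce_fit> patlak: vp = 0.008961, KTrans = 0.0001796 | SS = 0.0001611 over 17 frames

compare_models(fits)
#>         model k     AICc delta weight
#>  steady_state 1 -188.429 1.347 0.2387
#>        patlak 2 -189.776 0.000 0.4681
#>        mtofts 3 -188.841 0.935 0.2933
#> best model: patlak

estimate_cnr(Ct, fits$patlak)
#> [1] 7.152871
```

A single replicate is noisy (here K^Trans comes out at 1.8×10⁻⁴ against a
generating PS of 3×10⁻⁴); the *distributional* behaviour is what validates
the method. The drift experiment repeats simulate → drift → noise → Patlak
fit and summarises the bias of the estimates, here with a 0.08 %/min drift
of the kind measured in contrast-free sham scans:

```r
run_drift_experiment(sim_config(n_reps = 200, seed = 7, drift_rate = 8e-4))
#> <bias_summary> 200 replicates, drift = 0.08 %/min
#>        truth      mean        sd       bias
#> KTrans 3e-04 0.0005783 6.842e-05  0.0002783
#> vp     6e-03 0.0046920 1.578e-03 -0.0013080
```

The reading: ordinary scanner drift inflates K^Trans by ~2.8×10⁻⁴ min⁻¹ —
as large as the NAWM value itself — and depresses v_p, which is why
low-permeability DCE-MRI studies should measure and report drift.

A thin command-line front end over the same functions is installed at
`inst/cli/dcebbb` (`simulate`, `drift-experiment`, `fit`, `compare`,
`semiquant`, `vif-eval`, `pipeline`; JSON in, JSON out).

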