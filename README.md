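# dilvr

Feature-anchored modelling of mechanical-ventilator pressure and volume
waveforms, with breath-by-breath parameter estimation.

## What problem this solves

Ventilator waveforms carry detailed information about lung mechanics,
ventilator settings and patient–ventilator dyssynchrony, but they are
usually read by eye. The standard quantitative tool, the linear
single-compartment model

&nbsp;&nbsp;&nbsp;&nbsp;*P = E·V + R·V̇ + P₀*,

reduces every breath to an elastance and a resistance and cannot represent
features such as the plateau-pressure peaks seen with dyssynchrony. `dilvr`
implements the damage-informed lung-ventilator (DILV) model: pressure and
volume waveforms are reconstructed from modular components — a tanh-squashed
sinusoidal drive sin(2πθt − φ), first-order recursions for the inspiratory
and expiratory gradients (β parameters), leaky differencing for plateau
peaks, a short pulse for the low-volume pressure knee — each controlled by a
parameter tied to one waveform feature. The volume model has six parameters
beyond the shared respiratory frequency θ; the pressure model has fourteen.
The amplitude ratio of the two models is a model-derived lung compliance,

&nbsp;&nbsp;&nbsp;&nbsp;*C_d = A_v / A_p1*&nbsp;&nbsp;(ml/cmH₂O),

which decreases with lung injury and tracks the single-compartment
compliance. The package is for respiratory-physiology and critical-care
researchers who want interpretable, per-breath quantification of ventilator
waveforms in the lab or from ICU recordings.

It provides:

* waveform simulation (`simulate_volume()`, `simulate_pressure()`,
  `simulate_breath()`) from validated parameter objects, with bundled
  reference parameter sets (`dilv_presets()`);
* multi-start bounded nonlinear least-squares estimation per breath
  (`fit_breath()`), with the full solution distribution as the uncertainty
  readout (`summary()`, `start_table()`);
* the single-compartment comparator (`fit_sc()`) and a per-breath MSE-ratio
  comparison (`compare_models()`);
* the compliance readout (`dilv_compliance()`);
* synthetic ground-truth generators (`make_breath()`, `make_cohort()`),
  waveform CSV input/output and breath segmentation
  (`read_waveform()`, `segment_breaths()`);
* a command-line wrapper (`inst/cli/dilv.R`) with `simulate`, `synth`,
  `fit`, `compare` and `report` subcommands.

## Worked example

Fit one noisy synthetic mouse breath (1% amplitude noise) and read off the
compliance:

```r
library(dilvr)

b    <- make_breath(scenario_spec("healthy-like", noise_sd = 0.01, seed = 42))
pre  <- dilv_presets("healthy_mouse")
spec <- fit_spec(pre$volume, pre$pressure, n_starts = 20, seed = 1)
fit  <- fit_breath(b, spec)
fit
#> <dilv_breath_fit>
#> <dilv_fit: volume model> 20/20 starts converged, best MSE = 0.000117519
#>   free: theta, b1, phi1, beta1, beta2, Av
#> <dilv_fit: pressure model> 18/20 starts converged, best MSE = 0.140275
#>   free: b2, phi2, beta3, beta4, Ap1, Ap4
#>   theta = 0.6557 breaths/s; Cd = Av/Ap1 = 0.02902 ml/cmH2O

summary(fit$volume)
#> Multi-start fit summary: 20 converged starts, best MSE 0.000117519
#>  parameter    median       sem lo_bound  hi_bound frozen multimodal
#>      theta   0.65559 5.624e-04    0.010 1.000e+01  FALSE      FALSE
#>         a1   9.67000 0.000e+00    0.100 1.000e+03   TRUE      FALSE
#>         b1   0.60142 7.068e-04   -0.990 9.900e-01  FALSE      FALSE
#>       phi1   0.08249 1.406e-03   -6.283 6.283e+00  FALSE      FALSE
#>      beta1 119.49934 2.177e-01    1.000 5.000e+03  FALSE      FALSE
#>      beta2  28.43066 1.336e-03    1.000 5.000e+03  FALSE      FALSE
#>         Av   1.03200 4.493e-05    0.000 1.000e+05  FALSE      FALSE

dilv_compliance(fit$volume$best[["Av"]], fit$pressure$best[["Ap1"]])
#> Model-derived compliance Cd = Av/Ap1 = 1.032 / 35.56 = 0.02902 ml/cmH2O

fit_sc(b)   # the single-compartment comparator on the same breath
#> <sc_params> E = 33.02 cmH2O/ml, R = 0.5799 cmH2O.s/ml, P0 = -1.011 cmH2O (C = 0.03029 ml/cmH2O)
#>   pressure MSE = 3.74037 cmH2O^2
```

The generating values here were θ = 0.66, A_v = 1.03, A_p1 = 35.53: the fit
recovers the amplitude to 0.2%, the model-derived compliance (0.02902)
agrees with the single-compartment compliance (0.03029) to ~4%, and the
waveform model's pressure error (0.14 cmH₂O²) is ~27× below the linear
model's (3.74 cmH₂O²), because the linear model cannot follow the knee and
plateau shape. The per-parameter SEM columns quantify per-breath estimation
uncertainty over the multi-start distribution.

See `vignettes/dilv-model.Rmd` for the model construction, the numerical
conventions (burn-in, normalization, masks) and the estimation design.

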