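---
title: "Modelling ventilator waveforms with dilvr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ventilator waveforms with dilvr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 4)
library(dilvr)
```

## The problem

Mechanical ventilators stream pressure, volume and flow waveforms that
clinicians read by eye: the gradient of inspiration, the shape of the plateau
pressure, peaks that betray patient–ventilator dyssynchrony, the PEEP
baseline. The classical quantitative alternative — the single-compartment
equation of motion $P = E V + R \dot V + P_0$ — compresses all of this into
an elastance and a resistance and cannot represent features such as plateau
peaks at all.

`dilvr` implements a middle path: a damage-informed lung-ventilator (DILV)
model that *mathematizes the waveform itself*. Each waveform is built
constructively from a nominal periodic breath plus a small number of
localized, hypothesis-anchored deformations, each controlled by its own
parameter. Estimating the parameters breath by breath turns the waveform
into an interpretable feature vector, and the ratio of the volume and
plateau-pressure amplitudes yields a compliance readout,
$C_d = A_v / A_{p1}$.

## Model construction

Both sub-models start from a phase-shifted sinusoid thresholded through a
tanh into a near-rectangular periodic drive:

$$f_s = \sin(2\pi\theta t - \phi) - b, \qquad
  f_b = \tfrac{1}{2}\{\tanh(a f_s) + 1\}.$$

Here $\theta$ is the respiratory frequency (breaths/s, shared by the two
sub-models and the only coupling between them), $b$ sets the duty cycle
(the I:E ratio; $b = 0$ gives 1:1), $\phi$ the phase, and $a$ the transition
sharpness.

**Volume.** Two first-order recursions track the drive with different
per-sample smoothing factors,
$y_{i+1} = \tfrac{1}{\beta} f_{b,i+1} + (1 - \tfrac{1}{\beta}) y_i$,
one with the inspiratory constant $\beta_1$ and one with the expiratory
constant $\beta_2$. The first, masked by the drive and normalized, carries
the rising flank; the second, masked by the drive's complement, carries the
falling flank; their sum scaled by $A_v$ is the volume trace. Six parameters
beyond $\theta$: $a_1, b_1, \phi_1, \beta_1, \beta_2, A_v$.

**Pressure.** The same rise/fall construction (with $\beta_3$, $\beta_4$,
amplitude $A_{p1}$ — the plateau pressure above baseline) is augmented by
two further components: a plateau-peak term built by leaky differencing of
the drive, $y_{i+1} = \tfrac{1}{\beta_5}(y_i + \Delta f_{b,i+1})$, masked,
differenced again with $\beta_6$, rectified and scaled by $A_{p2}$ — this
produces the peaks at the beginning and end of the plateau associated with
ventilator dyssynchrony; and a low-volume knee term from a second, short
sinusoidal pulse ($a_3, b_3, \phi_3$) confined to the window where the main
component is small, scaled by $A_{p3}$. The constant $A_{p4}$ is the PEEP
baseline. Fourteen parameters beyond $\theta$. Setting $A_{p2} = 0$ or
$A_{p3} = 0$ removes the corresponding feature exactly, which is how the
healthy/injured mouse reference presets are encoded.

```{r waveforms}
g <- sample_grid(dt = 0.005, n = 1334) # two periods at theta = 0.3
b <- simulate_breath(volume_params(), pressure_params(), g)
plot(b)
```

## Numerical choices

A few decisions matter for anyone comparing implementations:

* **Recursion initialization and burn-in.** The recursions' initial values
  are arbitrary, so all terms are simulated with initial value 0 over a
  warm-up window that is discarded before masking and normalization. The
  warm-up spans at least `burn_in_periods` (default 3) breath periods and is
  extended automatically to eight time constants of the slowest recursion —
  $\beta$ samples for first-order tracking, but $1/\log\beta$ samples for
  leaky differencing, which matters because dyssynchrony fits push
  $\beta_5$ very close to 1. After this warm-up the traces are periodic to
  well below $10^{-4}$ of their amplitude.
* **Normalization denominators.** The rise/fall components are multiplied by
  their segment mask and divided by the maximum of the *raw* recursion
  vector over the (at least one full period) analysis window. Dividing by
  the masked maximum instead would make both segments peak at exactly 1 and
  their overlap at the inspiration–expiration transition would push the
  summed peak several percent above $A_v$ at soft sharpness values; with the
  raw-vector denominator the waveform peak equals the amplitude parameter,
  which is what makes $C_d = A_v/A_{p1}$ a meaningful amplitude ratio. The
  plateau-peak and knee components are normalized by the maximum of their
  final (masked) term, so their peaks equal $A_{p2}$ and $A_{p3}$ exactly.
  The generic `mask_normalize()` primitive, by contrast, implements the
  mask-then-normalize contract (peak exactly 1).
* **Expiratory masks.** As written, a literal transcription of the
  construction would mask the expiratory terms by the *inspiratory* drive,
  zeroing expiration and leaving $\beta_2/\beta_4$ inert — inconsistent with
  the role of those parameters. The package masks the expiratory terms by
  the drive's complement; `masks = "as-printed"` switches to the literal
  transcription for comparison.
* **Period coverage.** Public simulators require the grid to span at least
  one period $1/\theta$; internally the normalization window is always
  extended to a full period, so during estimation a free $\theta$ moving
  across the exact one-period boundary sees no discontinuity.
* **Units.** ml, cmH2O, seconds; $\theta$ in breaths/s. The $\beta$
  parameters are *per-sample* smoothing factors, hence comparable only at a
  fixed sampling step; `dt` (default 0.005 s, at least 200 samples per
  period for the bundled presets) is therefore an explicit part of the
  estimation configuration, and data are resampled to it before fitting.

## Estimation

Per breath and per sub-model, `fit_breath()` minimizes the mean squared
error between simulated and measured trace with bound-constrained
L-BFGS-B, from `n_starts` initializations drawn uniformly from an interval
centered on the configured values (default half-width 30% of each center).
The solution *distribution* over starts, not just its minimum, is the
uncertainty readout: `summary()` reports per-parameter median and standard
error of the mean over converged starts and flags multimodality when the
sorted solutions contain a gap wider than 10% of the parameter's bound
width. Design details:

* The objective surface has long, nearly flat curved valleys (small changes
  in $\theta$ compensated by phase and gradient parameters on a one-period
  window). Numerical-gradient L-BFGS-B stalls part-way along them, so each
  start is followed by a short Nelder-Mead polish (`polish_maxit`, default
  300 iterations) that reliably walks the valley floor; with it, noise-free
  synthetic breaths are recovered to well below 0.1%.
* $\theta$ is estimated within the volume fit and then frozen for the
  pressure fit (`theta_mode = "from_volume"`), keeping the two fits as
  independent as the model construction intends; `"joint"` optimizes the
  summed MSE instead, and `"fixed"` freezes $\theta$ at its configured
  value.
* Not every parameter is estimated in every setting. By default the drive
  sharpness ($a_1, a_2$), the knee group ($a_3, b_3, \phi_3, A_{p3}$) and
  the plateau-peak group ($\beta_5, \beta_6, A_{p2}$) are frozen at their
  configured values; the peak group is freed when fitting
  dyssynchrony-like data. Frozen parameters are returned bit-for-bit
  unchanged.
* Degenerate simulations inside the objective (e.g. a knee pulse that does
  not overlap the low-pressure window) return a large penalty rather than
  raising, so multi-start continues. Ties among equal-MSE optima resolve to
  the first in seed order, and the full distribution is always retained.
* All initialization draws derive from one seed, with a separate stream per
  sub-model, so a run is exactly reproducible and the first $k$ starts of a
  longer run coincide with a shorter run's — making the best MSE
  nonincreasing in `n_starts`.
* Initialization intervals and bounds are configurable, not canonical: the
  registry bounds (`dilv_parameters()`) are deliberately wide physical
  ranges, and the default half-width is a pragmatic choice for
  breath-to-breath tracking where the previous breath's estimate centers
  the next breath's search.

`compare_models()` fits both the DILV model and the single-compartment
comparator and reports the ratio of their *pressure* MSEs. The comparison
deliberately uses the pressure trace only: the single-compartment model
takes volume and flow as inputs, so pressure is the one quantity both
models predict, and a "combined" DILV error would add ml² to cmH2O².
Ratios below 1 favor the waveform model; on breaths with plateau peaks the
linear model cannot follow the peaks and the ratio drops well below 1.

## The synthetic generator

`scenario_spec()` / `make_breath()` / `make_cohort()` generate ground-truth
test data in four regimes built on the bundled reference presets: mouse-scale
healthy and injured pressure-controlled breaths (the injured regime has
lower $A_v$, faster expiration and lower $A_v/A_{p1}$), human-scale breaths
with plateau peaks ($A_{p2} > 0$, $\beta_5$ near 1) emulating ventilator
dyssynchrony, and single-compartment-generated breaths on which the linear
comparator is exact by construction. Noise is additive i.i.d. Gaussian per
sample, scaled to a fraction (default 1%) of the trace's peak-to-trough
amplitude — the simplest testable stand-in, since real sensor noise is
uncharacterized here. Breath-to-breath variability is multiplicative
Gaussian jitter on the generating parameters.

What the generator does *not* emulate bounds what passing tests show:
there is no autocorrelated or heteroscedastic sensor noise, no ventilator
controller dynamics, no drift within a breath sequence, and no
patient-triggered timing irregularity. Recovery results on this synthetic
data therefore demonstrate correctness and identifiability of the
estimation machinery under the model's own assumptions, not performance on
recorded clinical data.

## Problem sizes and accuracy checks

The package's self-checks use desk-scale problem sizes chosen to exercise
every claim: single breaths at `dt` = 0.005 s (300–600 samples per period),
cohorts of 10–20 breaths per regime, and 8–50 optimization starts per breath
(the full uncertainty workflow used 1,000 starts per breath; the
distributions are unimodal and narrow well before that). At 1% amplitude
noise with initializations within ±30% of the generating values, the pooled
median relative error of the free parameters stays below 5%, fitted
$A_v/A_{p1}$ ratios land within 5% of the generating ratio, and the injured
regime's fitted compliance falls below the healthy regime's — the direction
that matters clinically.

## Known limitations

* The DILV model is descriptive, not mechanistic: parameters quantify
  waveform features whose physiological interpretation is hypothesis-driven
  and mode-dependent (in pressure-controlled ventilation the pressure trace
  reflects the controller, not the lung).
* Pressure and volume are coupled only through $\theta$; no mechanical
  constraint links their shapes.
* The model is a sampled recursion, not an ODE; fitted $\beta$ values are
  tied to the sampling step.
* Structural identifiability is managed (parameter freezing, bounds,
  time-localized features), not proven; some groups ($a_3, b_3, \phi_3,
  A_{p3}$; $\beta_5, \beta_6, A_{p2}$) are known to trade off against each
  other.
* Breath segmentation assumes volume returns to a trough between breaths;
  modes with incomplete exhalation need manual segmentation.
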