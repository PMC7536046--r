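---
title: "Spectral early warning signals: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral early warning signals: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ewspec)
```

## The model behind the indicators

Consider a stochastic dynamical system fluctuating about a stable
equilibrium while a slowly drifting parameter carries it toward a local
codimension-1 bifurcation. For small additive noise the deviations from
equilibrium follow the linearized dynamics — an Ornstein–Uhlenbeck process
in continuous time, a linear autoregression in discrete time — whose
second-order statistics are available in closed form in terms of the
dominant eigenvalue(s) of the Jacobian and the noise amplitude σ. `ewspec`
evaluates these forms through `bifurcation_spec()` and the
`analytic_variance()` / `analytic_autocorrelation()` /
`analytic_power_spectrum()` / `analytic_smax()` family:

| family (domain)            | eigenvalue(s)                | variance        | ρ(τ)                   | S(ω) |
|----------------------------|------------------------------|-----------------|------------------------|------|
| Fold/TC/PF (continuous)    | λ < 0, λ → 0⁻                | −σ²/2λ          | e^{λ\|τ\|}             | σ²/2π · 1/(ω²+λ²) |
| Hopf (continuous)          | μ ± iω₀, μ → 0⁻              | −σ²/2μ          | e^{μ\|τ\|} cos ω₀τ     | σ²/4π · [1/((ω−ω₀)²+μ²) + 1/((ω+ω₀)²+μ²)] |
| Fold/TC/PF (discrete)      | 0 ≤ λ < 1, λ → 1⁻            | σ²/(1−λ²)       | λ^{\|τ\|}              | σ²/2π · 1/(1+λ²−2λcos ω) |
| Flip (discrete)            | −1 < λ ≤ 0, λ → −1⁺          | σ²/(1−λ²)       | λ^{\|τ\|}              | σ²/2π · 1/(1+λ²−2λcos ω) |
| Neimark–Sacker (discrete)  | r e^{±iθ}, r → 1⁻            | σ²/(1−r²)       | r^{\|τ\|} cos θτ       | σ²/4π · [1/(1+r²−2r cos(ω−θ)) + …] |

All spectra are densities over angular frequency: their integral over the
full domain (the real line, or (−π, π] for maps) equals the stationary
variance, a property the package enforces exactly in its estimators and
verifies by quadrature in its tests. Transcritical and pitchfork
bifurcations share the fold's forms, as the linearization cannot
distinguish them; the family is kept as metadata only. For the
two-dimensional Hopf and Neimark–Sacker dynamics we evaluate the forms for
a single observed coordinate and identify the per-coordinate noise
amplitude with the scalar σ (isotropic noise); how a bivariate oscillation
is reduced to the observed scalar is genuinely ambiguous in general, and
this is the simplest consistent convention.

Two practical consequences of the table drive the package's design. First,
the spectral peak S_max grows like σ²/μ² while the variance grows like
σ²/μ, so S_max reacts more strongly to shrinking stability margins and is
less sensitive to drifts in σ. `analytic_smax()` finds the peak by a
4096-point grid search plus golden-section refinement because the
two-Lorentzian Hopf form has no closed-form argmax; non-oscillatory
families return their peak at ω = 0 exactly, the flip at ω = π. Second, the
*sign* of an autocorrelation trend before an oscillatory bifurcation
depends on the lag: at lags near half the incipient period the indicator
falls rather than rises. Autocorrelation should therefore be read at
several lags, which `ews_config(ac_lags = ...)` makes routine.

## Spectrum estimation

`welch_spectrum()` averages Hamming-tapered, 50%-overlapping periodograms,
using the 1/n-normalized DFT convention (`periodogram()`), and rescales the
result so that the two-sided spectrum integrates exactly to the window's
sample variance (denominator n). The default segment length is 40 points —
the standard choice in rolling-window EWS software — capped at half the
input and shrunk, if necessary, so that at least three segments are
averaged. On the ~170-point windows of the model experiments this averages
about eight periodograms. We deliberately prefer this strongly averaged,
coarser estimate to longer segments: model selection among spectral shapes
(below) is only as reliable as the per-bin noise allows, and with only
three averaged segments the three-parameter Hopf form routinely overfits
chance bumps in fold-type spectra.

The DC bin is always excluded: the series is detrended upstream, so the
zero-frequency bin is an artifact. Mean removal (per segment) additionally
suppresses power throughout the taper's main lobe around DC, so the fitting
step also ignores a further `dc_guard = 1` lowest bin by default; treating
that contaminated bin as data would mimic an off-zero spectral peak.

## Classification by canonical spectral forms

`fit_form()` fits, by bounded Levenberg–Marquardt least squares on linear
power values, the three canonical continuous-time forms — fold Lorentzian,
Hopf double Lorentzian, flat null — to the estimated spectrum; these same
three forms are used even for discrete-time data, where the fold form plays
the role of "reddened" and the Hopf form, with ω̂₀ near π, captures the
flip signature. The null fit is the exact flat least-squares solution. Fold
and Hopf fits are initialized from the empirical peak frequency and the
spectral half-width at half maximum, with three perturbed restarts, keeping
the best residual sum of squares; ω₀ is bounded below by twice the
frequency resolution so the Hopf form cannot collapse onto the fold form.

AIC uses the Gaussian least-squares correspondence AIC = n ln(RSS/n) + 2k
with k = 2 (fold), 3 (hopf), 1 (null), an RSS floor of 10⁻¹² × total power
guarding against perfect fits. `classify_window()` applies the small-sample
correction (AICc) by default: with roughly 19 usable bins and up to three
parameters the samples-per-parameter ratio is far below the threshold at
which the model-selection literature recommends the correction, and omitting
it measurably inflates the win rate of the most flexible (Hopf) form on
non-oscillatory data. `akaike_weights()` converts the three scores into
normalized weights.

Like every indicator in the pipeline, the weights are computed on
stationary-block-bootstrap resamples of the window, and the *mean* weight
across resamples is the reported classification. This matters: a single
Welch estimate can contain a phase-coherent noise bump that the Hopf form
fits eagerly, but block resampling destroys such accidental alignments
while preserving the short-range correlation structure that distinguishes
the true spectral shapes. Averaging over resamples therefore yields a
markedly more stable classification than a single estimate, particularly
for fold-type windows.

## The rolling-window pipeline

`compute_ews()` truncates the series at the supplied pre-bifurcation time,
removes slow drift with a Lowess smoother (`stats::lowess`; span 0.2 of the
series by default, or an absolute time span such as 80 days for daily
chemostat-style data), and then slides a window of 40% of the truncated
series in steps of 10 over the residuals. Each window is summarized by its
variance (denominator n), lag-τ autocorrelations (the Pearson correlation
of the two lag-shifted subseries, the convention of common EWS software,
which is exactly −1 for an alternating sequence), S_max and, optionally,
AIC weights. With `n_bootstrap > 0`, each window is resampled by the
stationary block bootstrap — blocks start uniformly at random, lengths are
geometric with a data-driven mean (the smallest lag at which the sample ACF
drops below 1/e, bounded to [5, 40], so significant temporal correlations
are retained), concatenated with circular wrap-around — and all metrics are
recomputed per resample, yielding bootstrap means and percentile 95%
intervals. Trends are summarized by the tie-corrected Kendall τ of each
metric over window-end times.

Percentile bootstrap intervals for serial-dependence statistics approach
nominal coverage only slowly; the suite verifies ≥90% coverage of nominal
95% intervals for the lag-1 autocorrelation of an AR(1) process in a
long-series regime (n = 8000, mean block 300) where block-join bias is
negligible. On short windows the intervals should be read as variability
bands, not exact confidence statements.

## Simulators and study conditions

`simulate_normal_form_continuous()` integrates the normal forms (e.g.
dx/dt = α − x² + σξ(t) for the fold; the supercritical Hopf normal form in
two dimensions) by Euler–Maruyama with dt = 0.01 by default — additive
noise and weak convergence are all the spectral statistics require.
`simulate_normal_form_discrete()` iterates the map analogues (e.g.
x_{t+1} = x_t + α − x_t² + σε_t). Both reduce exactly to their
deterministic skeletons at σ = 0, report trajectory blow-ups with the first
crossing time, and are bitwise reproducible from their seed.

`simulate_ricker()` iterates the harvested Ricker map
N_{t+1} = N_t e^{r(1−N_t/K)+σε_t} − F N_t²/(N_t²+h²), clamping negative
values to zero. Note the noise is multiplicative (it acts through the
growth exponent), so the effective additive noise amplitude is
approximately σN — the mechanism by which variance fails as an indicator in
the harvesting scenario while S_max does not. The four study scenarios
(`make_scenario()`) run 500 steps at baseline parameters r = 0.75, K = 10,
F = 0, h = 0.75, σ = 0.04, ramping F linearly 0 → 2.7 (fold pair) or r
linearly 0.5 → 2.3 (flip pair); null scenarios hold the ramped parameter at
its initial ramp value, which the sources leave unspecified beyond "fixed".
Initial conditions default to the stable equilibrium of the initial
parameters, solved numerically. EWS are computed up to the step at which
the ramp crosses the deterministic bifurcation value (step 438 for the
fold at F = 2.364, step 417 for the flip at r = 2.000) — a reproducible
truncation rule, in contrast to detecting the transition empirically.
`ricker_bifurcation_points()` locates the fold by eliminating F through the
fixed-point condition and root-finding the tangency residual in N (two
tangencies exist; the collapse of the upper branch met as F increases is
the one at larger F), and the flip from the map derivative 1 − r at
N* = K.

## Evaluation

`run_ricker_experiment()` scores each forced and null realization by the
Kendall τ of each indicator over window-end times (τ is the package's trend
measure throughout; the last-window metric value is a configurable
alternative and discriminates more sharply in the flip experiment, but a
trend score is the choice that generalizes to settings where absolute
indicator levels are incomparable). Decreasing lag-1 autocorrelation is
used as the flip-scenario prediction, since the lag is half the incipient
period. `roc_auc()` sweeps a threshold over pooled scores; its trapezoidal
AUC equals the Mann–Whitney pair-counting probability, which the tests
verify exhaustively. Null realizations are truncated and windowed exactly
like their forced counterparts so the scores are comparable. All seeds
derive deterministically from one base seed.

At the scale of the packaged experiments (100 forced + 100 null per
scenario, windows of ~170 points, 10-step window spacing, 100-resample
dominance averaging) the full evaluation of both scenario pairs runs in a
few minutes on one core; these sizes are the package defaults and are what
the test suite and `scripts/acceptance.R` execute.

## What the synthetic experiments do and do not show

The generators emulate the study conditions: slow one-parameter ramps,
small environmental noise, a single observed variable, uniform sampling,
and (for the Ricker model) density-dependent noise. Passing tests
demonstrate that the indicators behave as the linearized theory predicts
*under those conditions*. They do not demonstrate robustness to features
real monitoring data often have — correlated or heavy-tailed noise,
irregular or sparse sampling, measurement error, multiple interacting slow
drivers, or transitions through global bifurcations, which produce no
critical slowing down at all. `make_chemostat_fixture()` generates
synthetic predator–prey-chemostat-style series (short, stationary,
damped-oscillatory, one per control-parameter value) for exercising the
fixed-parameter analysis path; it is labelled synthetic and is not a
substitute for experimental data.

## Known limitations

* The classifier distinguishes oscillatory from non-oscillatory
  bifurcations only; super- versus subcritical variants produce the same
  linearized spectra and require nonlinear information.
* All forms assume small noise and quasi-stationarity within a window;
  fast ramps or large noise invalidate the closed forms.
* The Hopf ω₀ lower bound (twice the frequency resolution) means
  oscillations slower than one cycle per half-segment cannot be
  distinguished from reddening at the default segment length.
* Degenerate inputs are handled conservatively: constant windows yield
  missing autocorrelations, all-zero spectra fit σ = 0 exactly, failed fits
  carry infinite AIC and zero weight, and all-tied trend series return
  Kendall τ = 0 by convention.
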