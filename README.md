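# ewspec: spectral early warning signals for tipping points

Many ecological, physiological and climate systems sit near *tipping points*
— local bifurcations at which a small parameter change triggers an abrupt
shift to a contrasting dynamical regime. Conventional early warning signals
(EWS) such as rising variance and lag-1 autocorrelation exploit critical
slowing down, but they are generic: they cannot tell an approaching
population collapse (Fold bifurcation) from the onset of oscillations (Hopf
or Flip bifurcation), and they can fail outright under density-dependent
noise.

`ewspec` implements *spectral* early warning signals, which extract more of
the information carried by a fluctuating time series:

* **Analytic forms.** Linearizing a stochastic system about its equilibrium
  yields an Ornstein–Uhlenbeck process (continuous time) or a linear
  autoregression (discrete time), for which the stationary variance, lag-τ
  autocorrelation ρ(τ) and power spectral density S(ω) have closed forms for
  *every* local codimension-1 bifurcation (Fold/Transcritical/Pitchfork,
  Hopf, Flip, Neimark–Sacker). For instance, near a continuous-time Fold
  with dominant eigenvalue λ → 0⁻ and noise amplitude σ,

      Var = −σ²/(2λ),   ρ(τ) = e^{λ|τ|},   S(ω) = (σ²/2π) · 1/(ω² + λ²),

  while a Hopf bifurcation with eigenvalues μ ± iω₀ produces Lorentzian
  spectral peaks at ±ω₀.

* **S_max.** The height of the spectral peak scales as σ²/μ², against σ²/μ
  for the variance: halving the distance to the bifurcation doubles the
  variance but *quadruples* S_max, making the peak a more sensitive and more
  noise-robust proximity indicator.

* **AIC-weight classification.** Fitting the canonical spectral forms
  S_fold(ω; σ, λ), S_hopf(ω; σ, μ, ω₀) and the flat null S_null(ω; σ) to an
  estimated (Welch) spectrum and converting the AIC scores into Akaike
  weights (w_fold, w_hopf, w_null) indicates *which kind* of transition is
  approaching — and, for oscillatory ones, at what frequency.

The package also provides the full inference pipeline (Lowess detrending,
rolling windows, stationary block bootstrap, Kendall-τ trend statistics),
stochastic simulators for the bifurcation normal forms and for a harvested
Ricker population model, and ROC/AUC evaluation of every indicator on
ensembles of forced versus null simulations.

## Worked example

The harvested Ricker model
`N_{t+1} = N_t exp(r(1 − N_t/K) + σε_t) − F N_t²/(N_t² + h²)`
(baseline r = 0.75, K = 10, h = 0.75, σ = 0.04) undergoes a Fold bifurcation
at F = 2.36 and a Flip (period-doubling) bifurcation at r = 2.00:

```r
library(ewspec)
unlist(ricker_bifurcation_points(ricker_params()))
#>   F_fold   r_flip
#> 2.363645 2.000000
```

Simulate the flip scenario (r ramped 0.5 → 2.3 over 500 steps) and compute
rolling-window EWS on the detrended series, truncated at the deterministic
bifurcation crossing (step 417):

```r
scenario <- make_scenario("flip_forced", seed = 1)
config <- ews_config(n_bootstrap = 0, metrics = c("variance", "ac", "smax"))
ews <- compute_ews(scenario$ts, config,
                   truncation_time = scenario$truncation_time)
ews
#> <ews_series> 26 windows of 167 points, metrics: variance, ac_1, ac_2, smax
#> Kendall tau:
#> variance     ac_1     ac_2     smax
#>    0.938   -1.000    0.735    0.908
```

The trend signature is characteristic of an approaching *oscillatory*
bifurcation: variance and S_max rise, lag-1 autocorrelation falls (the lag
equals half the incipient period T = 2) while lag-2 autocorrelation rises.
Classifying the last pre-bifurcation window confirms it and reads off the
oscillation frequency:

```r
det <- lowess_detrend(scenario$ts)
w <- attr(ews, "window_length")
late <- det$residuals$values[(417 - w + 1):417]
cls <- classify_window(late)
cls$weights
#> <aic_weights> fold 0.000 | hopf 1.000 | null 0.000
cls$fits$hopf
#> <spectrum_fit> hopf: sigma = 0.5387, mu = -0.2075, omega0 = 3.142; ...
oscillation_period(cls$fits$hopf$omega0_hat)
#> [1] 2
```

The fitted peak frequency ω₀ = π implies period-2 oscillations — exactly
what a Flip bifurcation produces.

## Command line

The installed `ewspec` script exposes the pipeline as subcommands:

```sh
ewspec simulate --scenario fold_forced --seed 1 --out traj.csv
ewspec ews      --input traj.csv --out-prefix ews_out --truncation-time 438
ewspec classify --input traj.csv --out fits.json
ewspec evaluate --scenario flip --n 100 --seed 1 --out-prefix flip_eval
```

Exit codes: 0 success, 2 usage error, 3 data error. Every run writes a
`.meta.json` provenance sidecar (tool version, subcommand, options).

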