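# argosmove

Behavioural-state analysis of Argos satellite tracks for movement
ecologists: from raw, irregular, error-prone satellite fixes to
transit/resident behavioural states, sex-specific movement estimates with
uncertainty, and residency summaries over Southern Ocean management areas.
The package was built around humpback whale migrations from coastal waters
to Southern Ocean feeding grounds, but every stage is generic to
Argos-tracked marine animals.

## What it computes

**Track regularization.** Argos fixes arrive irregularly with class-coded
errors (classes 3, 2, 1, 0, A, B). A first-difference correlated random
walk on a locally planar chart,

    x_t = x_{t-1} + gamma * (x_{t-1} - x_{t-2}) + eta_t,   eta_t ~ N(0, sigma^2),

is fitted by exact maximum likelihood (Kalman filter), with irregular
observations tied to a regular 6-h grid by linear interpolation weights and
per-class observation noise. Smoothed positions with standard deviations
come from the RTS smoother; multiple-imputation track realizations are
joint draws from the smoothing distribution.

**Behavioural states.** Step speeds and turning angles feed a 2-state
hidden Markov model — gamma(mu, sigma) step speeds, wrapped Cauchy(lambda,
kappa) turns — in four configurations: no sex effects, sex on the
transition probabilities, sex on the movement parameters, or both
(10/14/22/26 parameters). Fits are by quasi-Newton maximum likelihood on
link scales across all animals; AIC selects the configuration; Viterbi and
forward-backward decode the states; Rubin-style pooling across track
realizations (total variance `W + (1 + 1/m) B`) turns location uncertainty
into honest confidence intervals.

**Spatial summaries.** Per-whale maximum displacement, total track
distance, location counts and percent-resident overall and per management
area (CCAMLR boxes, IWC areas, MPA layer), arrival times into regions, and
1°×1° gridding of historical catch records.

**Ground-truthed simulation.** Every stage is testable without real data:
the simulator generates latent state sequences, great-circle movement
paths, Argos-degraded observations and catch records, with defaults
matching the published study scale (12 tracks of 425 six-hour steps).

## Worked example

```r
library(argosmove)

## 1. ground-truthed simulation -> Argos degradation -> regularization
set.seed(42)
mp <- movement_params(mu = c(5.15, 0.89), sigma = c(2.6, 0.45),
                      lam = c(0, pi), kappa = c(0.62, 0.1))
states <- simulate_state_sequence(transition_matrix(0.035, 0.017), 400)
path <- simulate_movement_path(states, mp, start = c(100, -38),
                               initial_bearing_rad = pi, id = "demo",
                               sex = "female")
obs <- degrade_to_argos(path)
fit <- fit_ssm(obs)
print(fit)
#> ssm_fit: 1216 obs -> 400 nodes (6 h grid), 1 segment(s)
#>   gamma = 0.350 (SE 0.039), sigma = 14.713 km (SE 0.447), loglik = -8602.47

## 2. features + the sex-dependent-movement HMM at study scale
series <- simulate_study_tracks(seed = 42)
hfit <- fit_hmm(series, config = 3, n_restarts = 2, seed = 42)
print(hfit)
#> fitted_hmm (config 3, sex on movement): 5100 obs / 12 tracks, 22 parameters
#>   loglik -15522.086, AIC 31088.171
#>   mean speed mu (km/h):
#>          female  male unknown
#> transit   4.957 3.298   4.028
#> resident  2.155 0.878   0.876

## 3. decoding and the implied long-run behaviour
decoded <- viterbi(hfit, series)
mean(decoded$state == series$true_state)   # 0.990
round(100 * stationary_distribution(hfit$pars$tpm$female), 1)
#>  transit resident
#>     33.6     66.4

## 4. published per-whale summaries
overall_summary(reported_track_summaries())
#> distance 6680 +/- 2620 km, displacement 4343 km, 5114 locations
```

The fitted speed means sit within a few percent of the generating values
(transit 5.15/3.16/4.00, resident 2.15/0.89/0.85 km/h for
female/male/unsexed), decoding recovers 99% of the true states, and the
estimated transition probabilities imply about two thirds of time in the
resident state.

A typical real-data run is one call:

```r
res <- run_pipeline(obs, sex = c(w1 = "female", w2 = "male"),
                    config = pipeline_config(m = 100, seed = 1),
                    out_dir = "out")
```

which writes regularized tracks, per-configuration fit JSONs, the pooled
parameter table, decoded states, per-whale summaries and a manifest.

## Layout

* `R/` — simulator, geodesy, SSM, features, HMM, pooling, spatial and
  catch summaries, pipeline.
* `src/forward.cpp` — scaled forward recursion (the fitting hot path).
* `inst/extdata/` — packaged per-whale summary table, pooled HMM
  estimates, simplified management-area GeoJSON.
* `vignettes/movement-hmm.Rmd` — models, assumptions, tunables, numerical
  choices, validation design, limitations.
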