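---
title: "Behavioural-state analysis of Argos tracks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioural-state analysis of Argos tracks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(argosmove)
```

## The problem

Satellite tags on migrating whales relay positions through the Argos system:
fixes arrive at irregular intervals, carry a six-level quality class
(3, 2, 1, 0, A, B, in decreasing accuracy), and the poorest classes are
wrong by several kilometres. Behavioural questions — when is the animal in
directed *transit* and when is it *resident* in a patch, does movement
differ between the sexes, how much time is spent inside management areas —
require a regular-in-time, error-reduced track and a latent-state model on
top of it. `argosmove` implements that chain end to end: state-space
regularization, step/turn feature extraction, a two-state hidden Markov
model (HMM) with sex covariates, multiple-imputation pooling, and spatial
residency summaries.

## Track regularization

The movement process on a locally planar chart is a first-difference
correlated random walk (DCRW) per axis,

$$x_t = x_{t-1} + \gamma\,(x_{t-1} - x_{t-2}) + \eta_t,
  \qquad \eta_t \sim N(0, \sigma^2),$$

on a regular 6-hour grid (four location estimates per day). An observation
at irregular time $\tau \in (t_{j-1}, t_j]$ is tied to the grid by linear
interpolation weights, $y = w\,x_j + (1-w)\,x_{j-1} + \varepsilon$ with
$w = (\tau - t_{j-1})/\Delta$, and $\varepsilon$ normal with a fixed
per-Argos-class standard deviation. With the state
$s_t = (x_t, x_{t-1})$ the model is linear-Gaussian, so

* the likelihood of $(\gamma, \sigma)$ is exact via the Kalman filter and
  maximized with `nlminb` (working scales $\tanh^{-1}\gamma$,
  $\log\sigma$);
* the location estimates and their standard deviations come from the
  Rauch–Tung–Striebel smoother; and
* multiple-imputation realizations are exact joint draws from the smoothing
  distribution via forward-filtering backward-sampling.

Assumptions worth stating: observation errors are isotropic normal rather
than the heavier-tailed errors Argos can produce (a deliberate
simplification, adequate for synthetic validation and conservative in the
sense that the class SDs are configurable); the two planar axes share
$(\gamma, \sigma)$ and are independent; and the chart is an azimuthal
equidistant projection about the track centroid, which keeps the state
equation linear at the cost of slowly growing distortion for tracks
spanning several tens of degrees. Data gaps longer than 7 days (the
`gap_split_days` tunable) split a track into independently gridded segments
that share movement parameters; how positions evolved across such
non-reporting gaps is unknowable from the data, so the per-gap net
displacement enters summaries only as an explicit, user-declared quantity.

Numerical choices: the first two states take a diffuse prior (variance
$10^4$ km$^2$) centred on the first observation; 2-by-2 solves fall back to
a $10^{-10}$ ridge when a predicted covariance degenerates (exactly-zero
noise limits); backward-sampling covariances are eigendecomposed with
negative eigenvalues clamped at zero.

## Movement features

Step speeds (km h$^{-1}$) are great-circle step lengths divided by the
6-hour step; turning angles are successive differences of forward azimuths
wrapped to $(-\pi, \pi]$, undefined for each segment's first step. All
geodesy uses one sphere of radius 6371.0088 km, shared with the simulator,
so feature extraction inverts the simulator exactly in the noiseless limit.
Speeds rather than raw step lengths are modelled because the per-state
means are reported in km h$^{-1}$; at a fixed 6-h step the two differ only
by a constant factor. The Southern Ocean filter keeps locations strictly
south of 36°S (`lat_cut = -36`); the boundary itself is excluded, a
documented convention, and runs broken by the filter are re-segmented so no
step spans removed locations.

## The two-state HMM

Per 6-h step the animal is in one of two latent states, transit or
resident, following a Markov chain with transition probability matrix
$\Gamma$. Emissions are a gamma density for step speed, parameterized by
mean $\mu$ and standard deviation $\varsigma$ (shape $\mu^2/\varsigma^2$,
scale $\varsigma^2/\mu$), and a wrapped Cauchy density for the turn,

$$f(\theta) = \frac{1}{2\pi}\,
  \frac{1-\kappa^2}{1+\kappa^2-2\kappa\cos(\theta-\lambda)},$$

with mean angle $\lambda$ and concentration $\kappa \in [0, 1)$. Four
configurations are compared: (1) no sex effects; (2) sex-specific
$\Gamma$; (3) sex-specific movement parameters ($\mu$, $\varsigma$,
$\kappa$); (4) both. Sex is a genuine three-level factor (female, male,
unknown) — unsexed animals get their own estimates rather than being pooled.
The turn mean $\lambda$ is estimated per state but never sex-varied: the
sex effects of interest act on step length and turn concentration, and
keeping $\lambda$ shared makes the parameter counts 10, 14, 22 and 26 for
configurations 1–4.

Fitting maximizes the likelihood summed over animals and segments, each
segment entering through a scaled forward recursion (implemented in C++)
with its initial distribution fixed at the stationary distribution of the
sex-appropriate $\Gamma$. Working scales are log for $\mu, \varsigma$,
logit for $\kappa$ and the transition probabilities, and plain radians for
$\lambda$: the wrapped Cauchy is periodic in $\lambda$, so an unconstrained
radian scale stays smooth where $\lambda$ sits near $\pm\pi$ (as it does in
residency), where a $\tan(\lambda/2)$ link degenerates. Optimization is
quasi-Newton (`nlminb`) from a moment-based initialization (speeds split at
the median; circular moments of the turns), with jittered restarts
(default 10); `nlminb`'s relative-, X- and singular-convergence exits are
all accepted as usable optima, singular convergence being routine when a
warm start sits on a ridge. States are relabelled after fitting so transit
has the larger mean speed, the scaled forward variables are floored at
$10^{-300}$, and a collapse diagnostic flags $\kappa > 0.995$ or
$\varsigma < 10^{-3}$. Exactly-zero speeds, for which the gamma density is
undefined, receive an estimated per-state point mass — the corresponding two
parameters are added only when zeros occur in the data.

Model selection uses AIC ($2k - 2\ell$), the field's default for these
models, with ties broken toward fewer parameters; BIC is available as an
option. Decoding offers both the Viterbi path (ties broken toward transit,
documented) and forward–backward posteriors.

## Multiple-imputation pooling

Location uncertainty propagates by refitting the selected HMM on each of
$m$ track realizations (default $m = 100$; desk-scale analyses use 10) and
pooling on the working scale by normal-theory rules: pooled estimate
$\bar{q}$, total variance $W + (1 + 1/m)B$ with $W$ the mean within-fit
variance (inverse Hessian) and $B$ the between-fit variance, and 95%
intervals $\bar{q} \pm z_{0.975}\sqrt{T}$ back-transformed. The pooling
rule is stated explicitly here because "pooled estimates and confidence
intervals" admits several conventions; percentile pooling of the
natural-scale estimates and a $t$-quantile with user-chosen degrees of
freedom are offered as options (small-$m$ corrections are not settled, so
the normal quantile is the default). Turn-mean estimates are circular and
are aligned to the first fit's branch before averaging, so realizations
straddling $\pm\pi$ do not cancel.

## Spatial summaries

Management areas are polygons (simplified longitude/latitude boxes in the
packaged GeoJSON; any GeoJSON with `name`/`category` properties can be
substituted). Point-in-polygon uses even-odd ray casting whose boundary
behaviour for axis-aligned boxes is exactly the documented convention:
south and west edges inclusive, north and east exclusive, so abutting areas
partition the plane. Locations in no CCAMLR area are labelled "Northern";
the MPA layer may overlap CCAMLR areas and is tallied separately. Per-whale
rows report maximum great-circle displacement from the deployment location,
total along-track distance (plus any declared non-reporting-gap net
displacement), location counts and percent-resident, the latter suppressed
below 10 locations; the overall row takes arithmetic means and $n-1$
standard deviations. Arrival time into a region is measured in fractional
days from a departure event, operationalized by default as the last
location north of the latitude cut before the first crossing — the
published definition ("leaving coastal waters") is not fully specified, so
the reference event is an explicit argument. Historical catch records are
summed into half-open 1°×1° cells by the floor convention, with half-open
longitude/latitude windows and inclusive year ranges.

## What the simulator does and does not emulate

The generator produces ground-truthed tracks: a two-state Markov chain per
6-h step, gamma speeds and wrapped Cauchy turns per state, great-circle
advancement on the sphere, and Argos degradation (exponential inter-fix
gaps, class mixture weighted toward A/B, isotropic per-class noise,
optional tag dropout). Its defaults are the study conditions: 12 tracks —
four females, four males, four unsexed — of 425 six-hour steps (about 5100
steps, the scale of the filtered Southern Ocean data), generated from the
published pooled estimates: transit $\mu$ 5.15/3.16/4.00 km h$^{-1}$
(female/male/unsexed), resident $\mu$ 2.15/0.89/0.85, transit $\kappa$
0.62/0.38/0.60, shared transitions Pr(R|T) = 0.035, Pr(T|R) = 0.017. Where
a generating value is not published it is a fixed package choice:
$\varsigma = \mu/2$ (a mid-range coefficient of variation for gamma step
models), resident $\kappa = 0.1$ (turn concentrations "close to zero" in
residency), $\lambda = 0$ in transit and $\pi$ in residency (directed
travel versus back-and-forth patch use), mean inter-fix gap 2 h, and the
per-class error SDs 0.25/0.5/1.5/4/6/10 km for classes 3/2/1/0/A/B. The
true inter-fix gap process of tags is unknown; exponential gaps are a
modelling choice, not an inference.

What passing tests therefore show: the estimators recover the parameters of
data generated under the model's own assumptions, at the study's scale, and
the pipeline's stages invert the simulator. What they cannot show: behaviour
under heavy-tailed Argos errors, duty-cycled transmission schedules,
behaviour-dependent surfacing, state dynamics that are not first-order
Markov, or emission distributions other than gamma/wrapped Cauchy. Real-data
conclusions inherit those caveats.

## Validation design and problem sizes

The test suite pairs every nontrivial computation with an independent
oracle: haversine/direct-geodesic references for the spherical primitives
(cross-checked against `geosphere` on a matched radius), exhaustive
enumeration of all $2^T$ state paths for the forward likelihood and Viterbi
decoding ($T \le 10$, tolerance $10^{-9}$), direct joint-Gaussian
conditioning for the DCRW smoother (5 nodes, tolerance $10^{-8}$, with a
moderate prior variance so both exact computations stay well conditioned),
ray-casting versus `mgcv::in.out` for point-in-polygon, and closed
forms/power iteration for the stationary distribution. Stochastic checks
use fixed seeds and tolerances of three Monte-Carlo standard errors.
Model recovery runs 20 replicates of the 12 × 425 default: the
sex-on-movement configuration must win AIC in at least 80% of replicates,
per-replicate speed means must land within 10% of truth, and the
replicate-averaged transition probabilities within 10% — transitions are
averaged across replicates because a single ~5100-step dataset determines a
probability of 0.035 only to about ±13% relative (one binomial standard
error), so the 10% band is a bias check, not a single-replicate precision
claim. Imputation-pooling coverage is checked on 40 replicates of a
proper-imputation Gaussian toy model (±5 percentage points around 95%), and
smoother coverage on 30 simulated tracks. These sizes are the package's
validation design; heavier replications change none of the conclusions,
only the Monte-Carlo error.

## Known limitations

* Observation errors are normal per class; no heavy-tailed option yet.
* The planar chart is track-local: circum-hemispheric tracks would need
  re-centring per segment.
* No land mask: simulated or smoothed positions can cross coastlines.
* The packaged management-area boxes are deliberate simplifications of the
  true boundaries; analyses needing legal-boundary precision must supply
  their own GeoJSON.
* Only two behavioural states and a sex covariate on transitions/movement;
  no time-varying or spatial covariates.
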