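---
title: "Methods: from dive signals to population dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from dive signals to population dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divepop)
```

`divepop` re-implements, as a tested and reusable pipeline, the analysis
chain used to link a marine predator's foraging behaviour to ocean-front
variability and population dynamics — the king penguin of the Crozet
archipelago being the motivating system. Because the original raw tracking,
dive, oesophageal-temperature, SST and count data are not publicly
deposited, the package pairs every analysis stage with a seeded
synthetic-data generator that emulates the statistical structure the stage
assumes and retains its ground truth. Passing tests therefore demonstrate
that the *methods* recover known truth under the stated study conditions,
not that the original field results are reproduced.

## The analysis chain

Two branches share a configuration ([`pipeline_config()`]):

1. **Dive branch.** Depth records sampled at 1–5 s are segmented into dives
   ([`detect_dives()`]); per-dive wiggle and step counts
   ([`count_wiggles()`], [`count_steps()`]), vertical rates and surface
   intervals feed a bout table ([`segment_bouts()`]). Oesophageal
   temperature drops are classified as prey ingestions
   ([`detect_feeding_events()`]). A negative-binomial regression of
   bout-level feeding counts on the bout covariates is ranked over all
   covariate subsets by QAIC, model-averaged with shrinkage, and validated
   by the concordance index ([`enumerate_and_average()`],
   [`cross_validate()`]).
2. **Ocean/population branch.** Gridded monthly SST yields per-month
   anomalies ([`anomalies()`]), a box-mean anomaly series south of the
   colony ([`box_ssta()`]), the polar-front latitude as the 5 °C surface
   isotherm ([`locate_pf()`]), and the leading EOF of anomalies over the
   combined South Atlantic–Indian domain — the subtropical dipole index
   ([`eof_leading()`]). Colony counts with missing cells are imputed by a
   Poisson log-linear colony × year model ([`impute_counts()`]); the island
   total is then fitted by a Bayesian stochastic Gompertz state-space model
   with one environmental covariate ([`fit_gompertz_ssm()`]). Annual
   breeding success is related to a covariate by a penalized
   cubic-regression-spline GAM ([`fit_gam()`]).

## The Gompertz state-space model

On log abundance $x_t = \ln N_t$:

$$x_{t+1} = x_t + r - b\,x_t + c\,z_t + \epsilon_t,\qquad
  \epsilon_t \sim N(0, \tau^2),$$
$$y_t = x_t + \eta_t,\qquad \eta_t \sim N(0, \sigma^2),$$

where $r$ is the growth rate at $N = 1$, $b$ the density-dependence
strength ($1-b$ is the lag-1 autocorrelation of log abundance; $b = 0$ is
density independence), $c$ the effect of a standardized covariate $z_t$,
$\tau$ the process-error s.d. and $\sigma$ the count (observation) error
s.d. Priors follow the conventions for long-lived seabirds: an informative
normal on the growth rate from the demographic-invariant argument,
$r \sim N(0.10, 0.02^2)$; weakly informative $N(0, 10^2)$ on $b$ and $c$;
uniform $(0, 3)$ on $\sigma$ and $\tau$; $x_1 \sim N(y_1, 1)$.

Sampling is by Gibbs, written in C++: the model is conditionally
linear-Gaussian, so latent states are drawn exactly by forward filtering /
backward sampling; $(r, b, c)$ jointly by a conjugate normal regression
update; $\tau^2$ and $\sigma^2$ by the truncated inverse-gamma conditionals
implied by the uniform priors on the s.d. scale. No tuning parameters, no
rejections; mixing for 30-year series is effectively immediate (split-chain
$\hat R < 1.01$ at 2 × 5,000 draws). The documented production
configuration is 2 chains × 50,000 draws after 10,000 burn-in
(`pipeline_config(mcmc = list(production = TRUE))`); the package default,
2 × 5,000 after 1,000, is statistically indistinguishable for these series
lengths and is what the tests and the acceptance script use.

**Identifiability.** Near the stationary state $x^* = r/b$ the likelihood
constrains mainly the drift $r - b\,\bar x$: $r$ and $b$ are individually
weakly identified, which is precisely why the informative demographic prior
on $r$ is used. Consequently the posterior of $r$ tracks its prior even for
long series, while $b$ is pinned jointly by the prior on $r$ and the
observed mean abundance. Simulation tests therefore check recovery under
truths consistent with the $r$ prior; with a deliberately wrong prior mean
the posterior of $b$ inherits a bias of roughly
$(\text{prior error})/\bar x$.

**Summaries.** [`summarize_posterior()`] reports posterior means, 95%
highest-probability-density intervals (shortest interval holding 95% of
draws), split-chain Gelman–Rubin $\hat R$, and $\Pr(c < 0)$, the posterior
probability that the covariate effect is negative.

## Dive-signal definitions

Depth is positive downward and vertical speed is $\Delta\text{depth} /
\Delta t$, positive while descending.

* **Dive**: maximal submerged interval (depth > 0.5 m) reaching the
  detection floor (3 m default; foraging-dive analyses refilter at 50 m,
  the bottom of the species' typical foraging range of 50–306 m).
* **Phases**: bottom = depth ≥ 80% of maximal depth (a common biologging
  convention); descent and ascent are the flanks. Phase rates are depth
  span over duration; typical planted values use the species' ~1.3 m/s.
* **Wiggle**: vertical speed crossing below zero and back within the
  descent+bottom phases — one count per down/up zero-crossing pair
  (overlapping sample triples merge). Ascent reversals are *not* counted:
  there the prevailing speed is already negative, so the definition is
  ill-posed; this choice is flagged here because other implementations
  differ.
* **Step**: maximal period within descent or ascent where |speed| falls to
  the 0.35 m/s threshold or below without reversing sign.
* **Feeding event**: the temperature trace is first segmented into drop
  episodes — a fall of ≥ `min_amplitude` (0.1 °C default) below the running
  baseline, ended once 80% of the drop is recovered — and an episode is an
  event when its steepest adjacent-sample descent reaches the calibrated
  0.06 °C/s criterion, with amplitude ≥ 0.1 °C and duration ≤ 300 s.
  Because episode boundaries do not depend on the rate threshold, the
  event count is monotone non-increasing in the threshold. Amplitude and
  duration cut-offs for the sensor used in the original calibration are
  not published; they are exposed as parameters, not claims.
* **Bout**: consecutive dives with post-dive surface intervals below a
  configurable gap (default 1800 s; the original criterion is unstated).
  Bout covariates are per-dive means except the dive count.
* **Thermocline**: depth of the maximum vertical temperature gradient after
  median-binning profiles to a 2-m grid and light running-mean smoothing;
  when the maximal gradient extends over a layer the layer midpoint is
  reported (so a linear 150–190 m transition yields ≈ 170 m).

## Prey-capture model

Counts of feeding events per bout are modelled as negative binomial with a
log link (`MASS::glm.nb`); when the dispersion parameter diverges
(equidispersed data) the Poisson boundary fit is substituted.
Overdispersion is checked two ways: the auxiliary regression of
$((y-\mu)^2 - y)/\mu$ on $\mu$ (one-sided), and the NB-versus-Poisson
likelihood ratio with the boundary-corrected null
$p = \tfrac12 P(\chi^2_1 > LR)$.

All-subsets enumeration covers the eight Table-style covariates with a
marginality constraint (the squared log-dive term only enters with the
linear term; 192 models). Models are ranked by
$\mathrm{QAIC} = -2\log L/\hat c + 2k$ with $\hat c$ the Pearson
$\chi^2/\mathrm{df}$ of the global model and $k$ counting the
variance-inflation parameter. Akaike weights $w_m \propto
e^{-\Delta_m/2}$; the 95% cumulative-weight confidence set is retained and
averaged with shrinkage ($\beta_{j,m} = 0$ where term $j$ is absent),
with unconditional standard errors
$\sqrt{\sum_m w_m (\mathrm{se}_{j,m}^2 + (\beta_{j,m}-\bar\beta_j)^2)}$
and per-term importance the summed weight of retained models containing the
term. Validation uses the concordance index (ties in prediction count one
half) on a held-out split, 36/38 by default, with standardization
parameters frozen from the fit rows.

Two design notes. First, covariates are centred and scaled, and the
quadratic dive-count term is the square of the *standardized* log dive
count: squaring after centring keeps the linear and quadratic columns near
orthogonal, without which neither coefficient is separately interpretable.
Second, simulation calibration shows the averaged estimator is essentially
unbiased but the unconditional-SE formula understates across-dataset
model-selection variability for borderline terms (coverage of ±2 SE ≈ 87–95%
rather than the nominal ≈ 95%); this is a property of the estimator itself,
inherited from its standard definition.

## Ocean products

Anomalies remove the per-cell, per-calendar-month climatology. The box
anomaly is the cos-latitude-weighted mean over 47–53° S, 49–55° E in
February–March. The front is located per longitude column of the 50–54° E
sector as the northernmost latitude where the (summer-mean) SST crosses
5 °C, by linear interpolation between grid rows; "summer" defaults to
January–March and is configurable because the source conventions mix
January–February and February–March windows. Front displacement converts
degrees latitude to km at 111.2 km/deg; colony distance is great-circle.
The dipole index is the leading principal component of
$\sqrt{\cos\varphi}$-weighted February–March anomalies over 10–50° S,
50° W–150° E (covariance PCA via SVD), standardized to unit variance, sign
fixed so a positive index means warm southwest quadrants of the two basins.
A covariance-based, $\sqrt{\cos\varphi}$-weighted PCA is standard EOF
practice; the original analysis does not state its weighting.

## What the generators emulate — and what they do not

* [`gen_dive_record()`] realizes exactly planted dives, wiggles (15% of
  maximal depth, within the bottom band) and steps (0.2 m/s plateaus in the
  descent) as a piecewise-linear trace sampled at 1/2/5 s. It does not
  emulate sensor drift, surface noise, or behaviourally realistic dive
  shapes beyond the features the detectors measure.
* [`gen_oesophageal_trace()`] uses a linear decline at the planted rate and
  exponential recovery (60 s constant; the true ingestion thermodynamics
  are unpublished — baseline 38 °C and the recovery constant are
  parameters, not claims). Drop amplitude scales with prey mass at
  0.06 °C/g so the smallest detectable prey (1.8 g) sits just above the
  default amplitude cut-off.
* [`gen_gompertz_series()`] simulates the state-space model forward from
  the stationary point of the published posterior means
  ($r = 0.101$, $b = 0.008$, $c = -0.067$, $\tau = 0.099$,
  $\sigma = 0.113$), i.e. about $3\times10^5$ breeding pairs.
* [`gen_colony_counts()`] draws Poisson (optionally NB) counts from a
  multiplicative colony × year model with random-walk year effects and
  masks exactly the requested fraction of cells (default 43.9%, ≈ 65
  observed colony-years for 4 × 30) while keeping every colony and year
  observed.
* [`gen_sst_fields()`] plants a unit-norm dipole pattern times a yearly
  standard-normal amplitude plus isotropic noise, calibrated so the mode
  explains the requested fraction (default 27%) of February–March variance
  over the EOF domain *under the analysis weighting*; and, in the front
  sector (47–56° S, 48–56° E), a linear-in-latitude base field with
  gradient $111.2/\text{slope}$ °C per degree plus a spatially uniform
  yearly anomaly, so the 5 °C isotherm responds to the measured box anomaly
  at exactly the planted slope (130 km/°C default). The dipole pattern is
  supported outside the front sector so the two planted signals do not
  contaminate each other. Real SST fields have spatially correlated noise,
  trends, and seasonal cycles richer than the emulated ones; the EOF
  recovery numbers here quantify sampling noise of the method, not
  HadISST-like behaviour.

## Breeding-success GAM

Gaussian GAM of success (a proportion, kept on the identity scale as in
the original analysis) on one covariate, penalized cubic regression spline
with 10 knots at covariate quantiles, smoothing by GCV. The F test of the
smooth, its p-value and the adjusted
$R^2 = 1 - \frac{RSS/(n-\mathrm{edf})}{TSS/(n-1)}$ (negative when worse
than a constant) are reported per covariate by [`gam_compare()`].
Limitations worth knowing: GCV undersmooths short series, so pure-noise
covariates can show spuriously positive adjusted $R^2$ at $n \approx 20$;
and with zero residual noise the GCV criterion is indifferent, so the
effective degrees of freedom of an exactly linear fit need not reach 1
although the fitted curve is the line.

## Numerical choices and degenerate inputs

* Imputation fits `count ~ colony + year` by IRLS to $10^{-10}$; a year (or
  colony) with no observation at all is an error, matching the
  requirement that year enter as a discrete term. The overdispersion factor
  (Pearson $\chi^2$/df) inflates imputed-cell standard errors.
* The Gibbs sampler floors residual sums of squares at $10^{-12}$ so exact
  noise-free series remain numerically valid; $\sigma$ can be pinned to 0,
  pinning states to observations (the autoregression reduction used as an
  oracle cross-check in the tests).
* Isotherm columns that never cross 5 °C are skipped with a warning; if all
  columns fail the front is undefined and an error is raised.
* Near-isothermal profiles (max gradient < 0.005 °C/m) return no
  thermocline, with a warning.
* Rank-sum comparisons are exact for small untied samples, normal with tie
  correction otherwise, and $p = 1$ when every value is tied.

## Problem sizes

The test-suite and acceptance-script sizes are chosen as the smallest at
which the statistical claims stabilize: Gompertz recovery uses 50
simulated 30-year series at 2 × 5,000 (+1,000) draws; front-slope and EOF
recovery use 20 replicate field sets (20 and 33 years); detector oracles
use 1,000 random traces; coefficient-recovery uses 100 data sets of 500
bouts. The full suite runs in roughly six minutes on one core.
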