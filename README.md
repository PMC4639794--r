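# divepop

Linking a diving seabird's foraging behaviour to ocean-front variability
and population dynamics: an R package for biologists working with
biologging records, gridded sea-surface temperature (SST) and colony count
series. The motivating system is the king penguin, which commutes from its
breeding colony to the Antarctic polar front — operationally, the 5 °C
summer surface isotherm — so that warm SST anomalies push its feeding
grounds south, lengthen its foraging trips and, through breeding success
and survival, depress the breeding population.

The package implements the full chain with seeded synthetic-data
generators (ground truth attached) standing in for the unreleased field
data:

* **Dive signals** — dive segmentation with descent/bottom/ascent phases;
  wiggles (depth reversals, a prey-pursuit proxy) and steps (slow-speed
  plateaus); oesophageal-temperature feeding events via the calibrated
  0.06 °C s⁻¹ drop-rate criterion; diving-bout construction; thermocline
  depth as the maximum vertical temperature gradient; rank-sum comparison
  of feeding rates between trip phases.
* **Prey-capture model** — negative-binomial regression of bout-level
  feeding counts on standardized dive covariates, all-subsets QAIC model
  averaging with shrinkage and unconditional SEs, overdispersion tests,
  concordance-index (C-index) cross-validation.
* **Ocean products** — monthly-climatology anomalies; cos-latitude box
  SSTA; polar-front latitude from the 5 °C isotherm per longitude column;
  the subtropical dipole index as the leading EOF of Feb–Mar anomalies
  over the combined South Atlantic–Indian domain; the front-shift-per-°C
  regression.
* **Population dynamics** — Poisson log-linear imputation of missing
  colony counts; a Bayesian stochastic Gompertz state-space model

  x_{t+1} = x_t + r − b·x_t + c·z_t + ε_t, ε_t ~ N(0, τ²),  y_t = x_t + η_t, η_t ~ N(0, σ²)

  with r ~ N(0.10, 0.02²), weak normal priors on b and c, uniform (0, 3)
  on σ and τ, sampled by a Gibbs/forward-filter-backward-sampler written
  in C++; posterior means, 95 % HPD intervals, Pr(c < 0) and split-chain
  R-hat.
* **Breeding success** — penalized cubic-regression-spline Gaussian GAM
  with GCV smoothing; F test, p and adjusted R² per covariate.

## Worked example

Simulate a 30-year count series under the published posterior-mean
parameterization (r = 0.101, b = 0.008, c = −0.067, τ = 0.099, σ = 0.113)
and refit it:

```r
library(divepop)
sim  <- gen_gompertz_series(n_years = 30, seed = 42)
post <- fit_gompertz_ssm(sim, chains = 2, iter = 5000, burnin = 1000, seed = 42)
summarize_posterior(post)
#> Stochastic Gompertz state-space posterior (10000 draws)
#>  parameter     mean hpd_lower hpd_upper  rhat
#>          r  0.10000   0.06080    0.1390 1.000
#>          b  0.00879   0.00393    0.0137 1.000
#>          c -0.09020  -0.14800   -0.0329 1.002
#>        tau  0.11900   0.05400    0.1850 1.006
#>      sigma  0.07540   0.00331    0.1290 1.014
#> Pr(c < 0) = 0.999
```

The posterior mean growth rate (0.100) and density dependence (0.0088)
sit on the simulation truth; Pr(c < 0) ≈ 1 flags the planted negative
covariate effect. The HPD of `b` excludes zero: density dependence is
detected.

The dive and ocean branches run the same way:

```r
trip  <- plan_foraging_trip(n_dives = 40, seed = 42)
rec   <- gen_dive_record(trip$plan, sampling_interval = 2, seed = 42)
dives <- dive_features(rec$record, detect_dives(rec$record, min_depth = 50))
nrow(dives); sum(dives$n_wiggles)
#> [1] 40
#> [1] 116          # exactly the planted wiggle count

sst <- gen_sst_fields(n_years = 33, seed = 1)
an  <- anomalies(sst$field)
pf_ssta_slope(locate_pf(sst$field), box_ssta(an))$slope
#> [1] 129.9        # km southward per degC; planted coupling was 130
100 * eof_leading(an)$explained_var
#> [1] 25.6         # percent; dipole mode planted at 27
```

`run_pipeline(pipeline_config(seed = 1), out_dir = "results/")` chains
everything end-to-end and writes per-stage CSV/JSON reports; every
threshold (0.06 °C s⁻¹, 0.35 m s⁻¹, the 5 °C isotherm, box and EOF
domains, MCMC sizes) lives in the config, which round-trips through YAML.

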