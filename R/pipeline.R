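#' Default pipeline configuration
#'
#' All thresholds and constants of the analysis chain in one nested list:
#' the feeding-event rate criterion (0.06 degC/s), the step speed threshold
#' (0.35 m/s), the 5 degC front isotherm, the anomaly box and dipole EOF
#' domain, prior and MCMC settings for the Gompertz state-space model, and
#' generator settings. `mcmc$production = TRUE` switches to the
#' full-length 2 x 50,000 (+10,000 burn-in) chains; the default desk-scale
#' run is 2 x 5,000 (+1,000).
#'
#' @param ... named overrides merged into the defaults (nested lists are
#'   merged recursively).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1,
    dive = list(min_depth = 3, foraging_min_depth = 50,
                step_speed_threshold = 0.35, bout_gap_threshold = 1800,
                bottom_frac = 0.8),
    feeding = list(rate_threshold = 0.06, min_amplitude = 0.1,
                   max_duration = 300, recovery_frac = 0.8,
                   smallest_prey_g = 1.8),
    ocean = list(isotherm = 5, pf_sector = c(50, 54), pf_months = 1:3,
                 box_lat = c(-53, -47), box_lon = c(49, 55),
                 box_months = c(2, 3), eof_lat = c(-50, -10),
                 eof_lon = c(-50, 150), eof_months = c(2, 3),
                 colony = list(lat = -46.43, lon = 51.86)),
    gompertz = list(r_mean = 0.10, r_sd = 0.02, bc_sd = 10, sd_max = 3),
    mcmc = list(chains = 2, iter = 5000, burnin = 1000, production = FALSE),
    synth = list(n_years = 30, n_bouts = 74, n_dives = 60,
                 sst_years = 33, missing_frac = 0.439, pf_slope = 130,
                 planted_var_frac = 0.27)
  )
  overrides <- list(...)
  if (length(overrides)) cfg <- utils::modifyList(cfg, overrides)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Write / read a pipeline configuration
#'
#' YAML round-trip for [pipeline_config()].
#'
#' @param config a `pipeline_config`.
#' @param path file path.
#' @return `read_config` returns a `pipeline_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  stop_if_not(file.exists(path), "config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  do.call(pipeline_config, cfg)
}

#' Run the full synthetic analysis chain
#'
#' Orchestrates both branches end-to-end on synthetic data:
#' dive branch — generate a foraging trip, detect dives/wiggles/steps and
#' feeding events, segment bouts, fit the QAIC-averaged NB prey-capture
#' model with a cross-validation split, and compare feeding rates between
#' trip phases; ocean/population branch — generate SST fields, compute
#' anomalies, the box SSTA, the front latitude series and the dipole EOF
#' index, regress front displacement on SSTA, generate and impute colony
#' counts, fit the Gompertz state-space model with the dipole index as
#' covariate, and fit the breeding-success GAM. Every stage is seeded from
#' `config$seed`; reruns with the same config are identical.
#'
#' @param config a `pipeline_config`.
#' @param out_dir optional directory; when given, per-stage CSV/JSON
#'   reports are written there.
#' @return list of class `pipeline_result` with one element per stage.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stop_if_not(inherits(config, "pipeline_config"), "not a pipeline_config")
  seed <- config$seed
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }
  mc <- config$mcmc
  if (isTRUE(mc$production)) {
    mc$iter <- 50000
    mc$burnin <- 10000
  }

  # --- dive branch -------------------------------------------------------
  dive_branch <- stage("dive_signal", {
    trip <- plan_foraging_trip(n_dives = config$synth$n_dives, seed = seed)
    simrec <- gen_dive_record(trip$plan, sampling_interval = 2, seed = seed)
    temp <- gen_oesophageal_trace(simrec, trip$ingestions, seed = seed)
    dives <- detect_dives(simrec$record, min_depth = config$dive$min_depth,
                          bottom_frac = config$dive$bottom_frac)
    foraging <- dives[dives$max_depth >= config$dive$foraging_min_depth, ]
    feats <- dive_features(simrec$record, foraging,
                           config$dive$step_speed_threshold)
    events <- detect_feeding_events(
      temp$record, config$feeding$rate_threshold,
      config$feeding$min_amplitude, config$feeding$max_duration,
      config$feeding$recovery_frac)
    bouts <- segment_bouts(feats, config$dive$bout_gap_threshold, events)
    prey_per_dive <- vapply(seq_len(nrow(feats)), function(j) {
      sum(trip$ingestions$dive == j)
    }, 0)
    phase_cmp <- phase_feeding_comparison(
      prey_per_dive[trip$phase == "front"],
      prey_per_dive[trip$phase == "transit"])
    list(trip = trip, dives = feats, events = events, bouts = bouts,
         phase_comparison = phase_cmp)
  })

  prey <- stage("prey_model", {
    sim <- gen_bout_table(n_bouts = config$synth$n_bouts, seed = seed)
    od <- overdispersion_tests(sim$table)
    cv <- cross_validate(sim$table, n_fit = 36, seed = seed)
    list(bouts = sim$table, overdispersion = od, cv = cv,
         model_set = cv$model_set)
  })

  # --- ocean / population branch ----------------------------------------
  ocean_res <- stage("ocean", {
    sst <- gen_sst_fields(n_years = config$synth$sst_years,
                          pf_slope = config$synth$pf_slope,
                          planted_var_frac = config$synth$planted_var_frac,
                          seed = seed)
    an <- anomalies(sst$field)
    ssta <- box_ssta(an, config$ocean$box_lat, config$ocean$box_lon,
                     config$ocean$box_months)
    pf <- locate_pf(sst$field, config$ocean$isotherm, config$ocean$pf_sector,
                    config$ocean$pf_months, config$ocean$colony)
    saiod <- eof_leading(an, config$ocean$eof_lat, config$ocean$eof_lon,
                         config$ocean$eof_months)
    slope <- pf_ssta_slope(pf, ssta)
    list(ssta = ssta, pf = pf, saiod = saiod, slope = slope, truth = sst$truth)
  })

  popdyn_res <- stage("popdyn", {
    counts <- gen_colony_counts(n_years = config$synth$n_years,
                                missing_frac = config$synth$missing_frac,
                                seed = seed)
    imp <- impute_counts(counts$table)
    # covariate and count series share their overlapping years
    n_common <- min(nrow(imp$series), nrow(ocean_res$saiod$index))
    stop_if_not(n_common >= 10,
                "need >= 10 overlapping covariate/count years, got %d", n_common)
    series <- data.frame(year = imp$series$year[seq_len(n_common)],
                         y = log(imp$series$total[seq_len(n_common)]),
                         z = ocean_res$saiod$index$pc[seq_len(n_common)])
    post <- fit_gompertz_ssm(series, chains = mc$chains, iter = mc$iter,
                             burnin = mc$burnin, priors = config$gompertz,
                             seed = seed)
    list(imputed = imp, posterior = post, summary = summarize_posterior(post),
         forecast = one_step_forecast(post))
  })

  breeding <- stage("breeding_gam", {
    z <- ocean_res$ssta$ssta
    bs <- gen_breeding_success(z, seed = seed)
    list(data = bs, gam = fit_gam(bs))
  })

  result <- structure(list(dive = dive_branch, prey = prey,
                           ocean = ocean_res, popdyn = popdyn_res,
                           breeding = breeding,
                           config = config,
                           mcmc_used = mc[c("chains", "iter", "burnin")]),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_reports(result, out_dir)
  result
}

# Per-stage CSV/JSON reports.
write_pipeline_reports <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(result$dive$bouts, file.path(out_dir, "bouts.csv"),
                   row.names = FALSE)
  utils::write.csv(result$ocean$pf, file.path(out_dir, "pf_series.csv"),
                   row.names = FALSE)
  utils::write.csv(result$ocean$ssta, file.path(out_dir, "box_ssta.csv"),
                   row.names = FALSE)
  utils::write.csv(result$ocean$saiod$index, file.path(out_dir, "saiod.csv"),
                   row.names = FALSE)
  utils::write.csv(result$popdyn$imputed$series,
                   file.path(out_dir, "counts_imputed.csv"), row.names = FALSE)
  avg <- result$prey$model_set$average
  gs <- result$popdyn$summary
  report <- list(
    mcmc = result$mcmc_used,
    seed = result$config$seed,
    prey_model = list(c_hat = result$prey$model_set$c_hat,
                      averaged = avg,
                      c_index_fit = result$prey$cv$c_fit$c_index,
                      c_index_validation = result$prey$cv$c_val$c_index),
    gompertz = list(summary = gs$table, pr_c_negative = gs$pr_c_negative),
    pf_slope_km_per_degC = result$ocean$slope$slope,
    saiod_explained_var = result$ocean$saiod$explained_var,
    breeding_gam = list(F = result$breeding$gam$F,
                        p = result$breeding$gam$p_value,
                        adj_r2 = result$breeding$gam$adj_r_squared))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
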