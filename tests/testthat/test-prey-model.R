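# NB regression, QAIC model averaging, concordance.

make_small_table <- function(n = 120, seed = 1) {
  gen_bout_table(n_bouts = n, seed = seed)$table
}

test_that("standardized design has exact moments and frozen reuse", {
  tab <- make_small_table()
  des <- bout_design(tab)
  expect_true(all(abs(colMeans(des$z)) < 1e-9))
  expect_true(all(abs(apply(des$z, 2, sd) - 1) < 1e-9))
  # freezing: same rows standardized with their own parameters round-trip
  des2 <- bout_design(tab, des$center, des$scale, des$log_center, des$log_scale)
  expect_equal(des$z, des2$z)
  # reversibility: de-standardizing recovers the raw max depth
  raw_back <- des$z[, "max_depth"] * des$scale["max_depth"] +
    des$center["max_depth"]
  expect_equal(unname(raw_back), tab$max_depth)
})

test_that("intercept-only NB fit on constant counts returns log mean", {
  tab <- make_small_table(30)
  tab$n_events <- 5L
  fit <- fit_nb(tab, character(0))
  expect_equal(unname(fit$coefficients[1]), log(5), tolerance = 1e-6)
  expect_equal(unname(fit$fitted[1]), 5, tolerance = 1e-6)
})

test_that("NB log-likelihood dominates Poisson on the same data", {
  tab <- make_small_table(200, seed = 3)
  od <- overdispersion_tests(tab)
  expect_gte(od$logLik_nb, od$logLik_poisson - 1e-6)
})

test_that("NB regression recovers a planted wiggle effect at large n", {
  sim <- gen_bout_table(n_bouts = 2000,
                        beta = c(intercept = 3.13, n_wiggles = 0.32),
                        theta = 2, seed = 8)
  fit <- fit_nb(sim$table, "n_wiggles")
  expect_equal(unname(fit$coefficients["n_wiggles"]), 0.32, tolerance = 0.16)
  expect_lt(abs(fit$coefficients["n_wiggles"] - 0.32), 0.05)
})

test_that("overdispersion tests reject for NB data and not for Poisson", {
  nb <- gen_bout_table(n_bouts = 1000, theta = 1, seed = 5)
  res <- overdispersion_tests(nb$table)
  expect_lt(res$dispersion$p_value, 1e-4)
  expect_lt(res$lrt$p_value, 1e-4)
  # Poisson null: LRT non-significant for most seeds
  rej <- vapply(1:10, function(s) {
    po <- gen_bout_table(n_bouts = 5000, theta = Inf, seed = 100 + s)
    overdispersion_tests(po$table)$lrt$p_value < 0.05
  }, TRUE)
  expect_lte(mean(rej), 0.10)
})

test_that("QAIC arithmetic and ranking invariance", {
  f <- list(logLik = -100, k = 3)
  expect_equal(qaic(f, c_hat = 2), 106)
  expect_equal(qaic(f, c_hat = 1), -2 * -100 + 2 * 3) # AIC when c_hat = 1
  expect_warning(v <- qaic(f, c_hat = 0.5), "clamped")
  expect_equal(v, 206)
  # shared c_hat never reorders models
  set.seed(6)
  fits <- lapply(1:10, function(i) list(logLik = -runif(1, 50, 150),
                                        k = sample(1:6, 1)))
  a <- order(vapply(fits, qaic, 0, c_hat = 1))
  b <- order(vapply(fits, qaic, 0, c_hat = 1) / 1) # same scale
  expect_equal(a, b)
  q1 <- vapply(fits, qaic, 0, c_hat = 2.5)
  q0 <- vapply(fits, function(f) -2 * f$logLik / 2.5 + 2 * f$k, 0)
  expect_equal(q1, q0)
})

test_that("Akaike weights follow the closed form", {
  # Delta {0, 2} -> weights {0.731, 0.269}
  w <- exp(-c(0, 2) / 2)
  w <- w / sum(w)
  expect_equal(round(w, 3), c(0.731, 0.269))
  tab <- make_small_table(150, seed = 9)
  ms <- enumerate_and_average(tab)
  expect_equal(sum(ms$models$weight), 1, tolerance = 1e-9)
  expect_gte(sum(ms$models$weight[ms$models$in_conf_set]), 0.95)
  expect_true(any(ms$models$in_conf_set))
  # marginality: squared term never enters without the linear term
  bad <- grepl("log_n_dives_sq", ms$models$subset) &
    !grepl("log_n_dives\\+|log_n_dives$|^log_n_dives", ms$models$subset)
  expect_false(any(bad))
})

test_that("model averaging shrinks and matches a single-model edge case", {
  tab <- make_small_table(150, seed = 10)
  full <- fit_nb(tab, divepop:::BOUT_TERMS)
  # confidence level ~ 0 keeps only the best model: averaged = its coefs
  ms1 <- enumerate_and_average(tab, conf_level = 1e-9)
  best_terms <- strsplit(ms1$models$subset[1], "\\+")[[1]]
  bf <- fit_nb(tab, setdiff(best_terms, "(intercept)"))
  avg <- ms1$average
  for (nm in names(bf$coefficients)) {
    expect_equal(avg$estimate[avg$term == nm], unname(bf$coefficients[nm]),
                 tolerance = 1e-6)
  }
  # a term absent from every retained model is averaged to exactly zero
  absent <- setdiff(avg$term[avg$estimate == 0], names(bf$coefficients))
  expect_true(all(avg$importance[avg$term %in% absent] == 0))
})

test_that("concordance index matches hand counts and brute force", {
  expect_equal(c_index(c(1, 2, 3), c(0.1, 0.2, 0.3))$c_index, 1)
  expect_equal(c_index(c(1, 2, 3), c(0.3, 0.2, 0.1))$c_index, 0)
  r <- c_index(c(1, 1, 2, 3), c(5, 7, 6, 6))
  expect_equal(r$c_index, 0.5) # (2 concordant + 0.5 tie) / 5
  expect_equal(r$n_comparable, 5)
  expect_warning(u <- c_index(c(2, 2, 2), c(1, 2, 3)), "tied")
  expect_true(is.na(u$c_index))
  set.seed(14)
  for (i in 1:20) {
    n <- sample(5:60, 1)
    obs <- sample(0:5, n, replace = TRUE)
    if (length(unique(obs)) == 1) obs[1] <- obs[1] + 1
    pred <- round(runif(n), 2)
    expect_equal(c_index(obs, pred)$c_index, oracle_c_index(obs, pred))
  }
})

test_that("cross-validation freezes standardization and refuses leakage", {
  tab <- make_small_table(74, seed = 15)
  expect_error(cross_validate(tab, fit_rows = 1:40, val_rows = 35:74),
               "leakage")
  cv <- cross_validate(tab, fit_rows = 1:36, val_rows = 37:74)
  expect_equal(length(cv$fit_rows), 36)
  expect_equal(length(cv$val_rows), 38)
  expect_true(cv$c_val$c_index >= 0 && cv$c_val$c_index <= 1)
  # standardization parameters come from the fit rows only
  des_fit <- bout_design(tab[1:36, ])
  expect_equal(cv$model_set$design$center, des_fit$center)
  # strong planted signal: validation concordance well above chance
  expect_gt(cv$c_val$c_index, 0.7)
})

test_that("zero-signal data gives chance-level concordance", {
  sims <- vapply(1:5, function(s) {
    sim <- gen_bout_table(n_bouts = 74, beta = c(intercept = 3), theta = 2,
                          seed = 50 + s)
    cv <- suppressWarnings(cross_validate(sim$table, fit_rows = 1:36,
                                          val_rows = 37:74))
    cv$c_val$c_index
  }, 0)
  expect_lt(abs(mean(sims) - 0.5), 0.12)
})
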