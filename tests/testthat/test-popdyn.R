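# Imputation and the Gompertz state-space sampler.

test_that("2x3 toy table imputes by iterative proportional fitting", {
  tab <- data.frame(colony = rep(c("A", "B"), 3),
                    year = rep(1:3, each = 2),
                    count = c(100, 10, 200, 20, NA, 30))
  imp <- impute_counts(tab)
  # year effect 1.5x from colony B, colony ratio 10 -> imputed A-year3 = 300
  expect_equal(imp$cells$filled[imp$cells$imputed], 300, tolerance = 1e-6)
  expect_equal(imp$series$total, c(110, 220, 330), tolerance = 1e-6)
  # complete multiplicative table: fitted = observed, totals = plain sums
  tab2 <- data.frame(colony = rep(c("A", "B"), 3), year = rep(1:3, each = 2),
                     count = c(100, 10, 200, 20, 300, 30))
  imp2 <- impute_counts(tab2)
  expect_equal(imp2$cells$fitted, imp2$cells$count, tolerance = 1e-6)
  expect_equal(imp2$series$total, c(110, 220, 330))
  # a year never observed is an error
  tab3 <- tab
  tab3$count[tab3$year == 3] <- NA
  expect_error(impute_counts(tab3), "no observation")
})

test_that("imputation error on a 43.9%-masked table is small and bounded", {
  sim <- gen_colony_counts(4, 30, missing_frac = 0.439, seed = 17)
  expect_equal(sum(!is.na(sim$table$count)), 67) # ~65 observed colony-years
  imp <- impute_counts(sim$table)
  truth <- sim$truth$counts[sim$masked]
  est <- imp$cells$filled[imp$cells$imputed]
  rel_err <- abs(est - truth) / truth
  # Poisson counts of this size have ~2-3% relative noise; the year x colony
  # model should impute within a few multiples of that
  expect_lt(median(rel_err), 0.05)
  expect_gte(imp$overdispersion, 0)
})

test_that("sigma = 0 fit matches the independent conjugate-regression Gibbs", {
  sim <- gen_gompertz_series(200, tau = 0.1, sigma = 0, seed = 23)
  post <- fit_gompertz_ssm(sim, iter = 10000, burnin = 1000,
                           sigma_fixed = 0, seed = 23, save_states = FALSE)
  mine <- do.call(rbind, post$draws)
  set.seed(23)
  orc <- oracle_gompertz_regression(sim$series$y, sim$series$z,
                                    n_iter = 20000)
  for (p in c("r", "b", "c", "tau")) {
    mcse <- sqrt(var(mine[[p]]) / nrow(mine) + var(orc[, p]) / nrow(orc))
    # conservative allowance for autocorrelated chains
    expect_lt(abs(mean(mine[[p]]) - mean(orc[, p])), 8 * mcse + 1e-4)
  }
})

test_that("degenerate deterministic series concentrates r at the mean growth", {
  g <- gen_gompertz_series(20, r = 0.12, b = 0, c_cov = 0, tau = 0, sigma = 0,
                           z = rep(0, 20), x1 = 5)
  post <- fit_gompertz_ssm(g, iter = 3000, burnin = 500, sigma_fixed = 0,
                           seed = 2, save_states = FALSE)
  d <- do.call(rbind, post$draws)
  # likelihood is exact (zero residual variance); posterior hugs r = 0.12
  expect_equal(mean(d$r), 0.12, tolerance = 0.02)
  expect_lt(sd(d$r), 0.01)
})

test_that("posterior summaries: HPD, Pr(c<0), R-hat behave as defined", {
  set.seed(31)
  g <- gen_gompertz_series(30, seed = 31)
  post <- fit_gompertz_ssm(g, iter = 3000, burnin = 500, seed = 31)
  s <- summarize_posterior(post)
  expect_true(all(s$table$hpd_lower <= s$table$mean))
  expect_true(all(s$table$mean <= s$table$hpd_upper))
  expect_true(all(s$table$rhat < 1.05))
  expect_true(s$pr_c_negative >= 0 && s$pr_c_negative <= 1)
  # HPD of a standard normal sample is close to +/- 1.96
  x <- rnorm(1e6)
  h <- divepop:::hpd_interval(x, 0.95)
  expect_equal(unname(h["lower"]), -1.96, tolerance = 0.01)
  expect_equal(unname(h["upper"]), 1.96, tolerance = 0.01)
  # all-negative draws give Pr(c<0) = 1
  fake <- post
  fake$draws <- lapply(fake$draws, function(d) { d$c <- -abs(d$c) - 1e-6; d })
  expect_equal(summarize_posterior(fake)$pr_c_negative, 1)
  # two chains from the same distribution: R-hat near 1
  expect_lt(divepop:::split_rhat(list(rnorm(5000), rnorm(5000))), 1.01)
})

test_that("c = 0 truth gives Pr(c<0) near one half on average", {
  # Pr(c<0) is nearly uniform across datasets when c = 0, so averaging needs
  # many seeds before its mean settles near one half
  pr <- vapply(1:100, function(s) {
    g <- gen_gompertz_series(30, c_cov = 0, seed = 300 + s)
    post <- fit_gompertz_ssm(g, iter = 1500, burnin = 300, seed = s,
                             save_states = FALSE)
    d <- do.call(rbind, post$draws)
    mean(d$c < 0)
  }, 0)
  expect_lt(abs(mean(pr) - 0.5), 0.15)
})

test_that("density independence: b = 0 truth is covered by the posterior", {
  cover <- vapply(1:20, function(s) {
    # growth rate consistent with the informative prior; without that the
    # prior's pull on r leaks into b through their collinearity
    g <- gen_gompertz_series(30, r = 0.10, b = 0, c_cov = 0, x1 = 10,
                             seed = 400 + s)
    post <- fit_gompertz_ssm(g, iter = 2000, burnin = 500, seed = s,
                             save_states = FALSE)
    tab <- summarize_posterior(post)$table
    row <- tab[tab$parameter == "b", ]
    row$hpd_lower <= 0 && 0 <= row$hpd_upper
  }, TRUE)
  expect_gte(mean(cover), 0.8)
})

test_that("b is data-dominated for long series while r tracks its prior", {
  # near the stationary state r and b*x are nearly collinear, so the growth
  # rate is weakly identified — the reason an informative demographic prior
  # is placed on r. The density-dependence strength, by contrast, is pinned
  # by the data for a long series regardless of the r prior.
  g <- gen_gompertz_series(1000, seed = 51)
  fits <- lapply(c(0.05, 0.15), function(pm) {
    post <- fit_gompertz_ssm(g, iter = 2000, burnin = 500,
                             priors = list(r_mean = pm), seed = 5,
                             save_states = FALSE)
    colMeans(do.call(rbind, post$draws))
  })
  b_means <- vapply(fits, `[[`, 0, "b")
  # b shifts with the r prior by Delta r / xbar (the collinear direction)
  expect_true(all(abs(b_means - 0.008) < 0.02))
  # the drift at the observed mean abundance is data-determined even though
  # r and b individually follow the prior
  xbar <- mean(g$series$y)
  drift <- vapply(fits, function(f) f[["r"]] - f[["b"]] * xbar, 0)
  expect_lt(abs(drift[1] - drift[2]), 0.005)
  # the covariate effect is unaffected by the r prior
  c_means <- vapply(fits, `[[`, 0, "c")
  expect_lt(abs(c_means[1] - c_means[2]), 0.005)
})

test_that("posterior predictive band has near-nominal coverage", {
  g <- gen_gompertz_series(30, seed = 61)
  post <- fit_gompertz_ssm(g, iter = 3000, burnin = 500, seed = 61)
  set.seed(61)
  fc <- one_step_forecast(post)
  inside <- mean(fc$observed >= fc$lower & fc$observed <= fc$upper)
  expect_gte(inside, 0.9) # well-specified data: band holds ~95% of years
})

test_that("uniform prior truncation keeps tau and sigma inside (0, 3)", {
  g <- gen_gompertz_series(12, tau = 1.5, sigma = 1.5, seed = 71)
  post <- fit_gompertz_ssm(g, iter = 2000, burnin = 200, seed = 71,
                           save_states = FALSE)
  d <- do.call(rbind, post$draws)
  expect_true(all(d$tau > 0 & d$tau < 3))
  expect_true(all(d$sigma > 0 & d$sigma < 3))
})
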