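# Dive, wiggle, step, feeding-event, bout and thermocline extraction.

test_that("detect_dives recovers V-dive geometry and rates", {
  # 0 -> 100 m -> 0 over 160 s at 1 Hz: both rates 1.25 m/s
  tt <- 0:160
  depth <- c(seq(0, 100, length.out = 81), seq(100, 0, length.out = 81)[-1])
  dives <- detect_dives(data.frame(time = tt, depth = depth), min_depth = 50)
  expect_equal(nrow(dives), 1)
  expect_equal(dives$max_depth, 100)
  expect_equal(dives$descent_rate, 1.25, tolerance = 1e-6)
  expect_equal(dives$ascent_rate, 1.25, tolerance = 1e-6)
  # flat surface trace: no dives
  flat <- data.frame(time = 0:100, depth = rep(0, 101))
  expect_equal(nrow(detect_dives(flat)), 0)
  # empty record: empty list
  expect_equal(nrow(detect_dives(flat[0, ])), 0)
})

test_that("dive phases partition the dive", {
  trip <- plan_foraging_trip(n_dives = 20, seed = 11)
  sim <- gen_dive_record(trip$plan, sampling_interval = 2, seed = 11)
  dives <- detect_dives(sim$record, min_depth = 3)
  rec <- sim$record
  for (j in seq_len(nrow(dives))) {
    d <- dives[j, ]
    desc <- rec$time[d$bottom_start_idx] - rec$time[d$start_idx]
    bott <- rec$time[d$bottom_end_idx] - rec$time[d$bottom_start_idx]
    asc <- rec$time[d$end_idx] - rec$time[d$bottom_end_idx]
    expect_equal(desc + bott + asc, d$duration)
    expect_gte(desc, 0); expect_gte(bott, 0); expect_gte(asc, 0)
  }
})

test_that("wiggle counting matches the three-point definition", {
  # depth [100,102,101,103,104] at 1 Hz: speeds [2,-1,2,1] -> one wiggle
  rec <- data.frame(time = 0:4, depth = c(100, 102, 101, 103, 104))
  dive <- data.frame(start_idx = 1, end_idx = 5, bottom_start_idx = 1,
                     bottom_end_idx = 5)
  expect_equal(count_wiggles(dive, rec), 1L)
  # monotone descent then ascent: zero wiggles (ascent excluded)
  v <- gen_dive_record(dive_plan(0, 120), sampling_interval = 1)
  dv <- detect_dives(v$record, min_depth = 50)
  expect_equal(count_wiggles(dv[1, ], v$record), 0L)
})

test_that("step counting finds slow plateaus in descent only", {
  # constant-speed descent at 1.3 m/s: no steps
  v <- gen_dive_record(dive_plan(0, 120), sampling_interval = 1)
  dv <- detect_dives(v$record, min_depth = 50)
  expect_equal(count_steps(dv[1, ], v$record), 0L)
  # descent with one slow plateau: one step
  s <- gen_dive_record(dive_plan(0, 120, n_steps = 1), sampling_interval = 1)
  ds <- detect_dives(s$record, min_depth = 50)
  expect_equal(count_steps(ds[1, ], s$record), 1L)
})

test_that("planted wiggle and step counts are recovered at 1, 2 and 5 s", {
  trip <- plan_foraging_trip(n_dives = 30, seed = 21)
  for (dt in c(1, 2, 5)) {
    sim <- gen_dive_record(trip$plan, sampling_interval = dt, seed = 21)
    feats <- dive_features(sim$record, detect_dives(sim$record, min_depth = 3))
    expect_equal(feats$n_wiggles, trip$plan$n_wiggles,
                 info = paste("wiggles at dt =", dt))
    expect_equal(feats$n_steps, trip$plan$n_steps,
                 info = paste("steps at dt =", dt))
  }
})

test_that("wiggle and step counts equal the brute-force definitional scan", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(20:60, 1)
    rec <- random_depth_trace(n)
    b0 <- sample(2:(n - 2), 1)
    b1 <- sample(b0:(n - 1), 1)
    dive <- data.frame(start_idx = 1, end_idx = n, bottom_start_idx = b0,
                       bottom_end_idx = b1)
    expect_equal(count_wiggles(dive, rec),
                 oracle_wiggles(rec$depth, rec$time, 1, b1))
    thr <- runif(1, 0.1, 1)
    expect_equal(count_steps(dive, rec, thr),
                 oracle_steps_phase(rec$depth, rec$time, 1, b0, thr, 1) +
                   oracle_steps_phase(rec$depth, rec$time, b1, n, thr, -1))
  }
})

test_that("feeding-event detection applies the rate threshold", {
  tt <- seq(0, 2000, by = 1)
  ing <- data.frame(time = c(200, 800, 1400), mass = 10)
  tr <- gen_oesophageal_trace(tt, ing, drop_rate = c(0.10, 0.05, 0.07))
  ev <- detect_feeding_events(tr$record, rate_threshold = 0.06,
                              min_amplitude = 0.01, max_duration = 1e6)
  expect_equal(nrow(ev), 2) # 0.05 degC/s drop is sub-threshold
  # constant trace: no events
  flat <- data.frame(time = tt, temperature = rep(38, length(tt)))
  expect_equal(nrow(detect_feeding_events(flat)), 0)
  # smallest-prey parameterization still detected
  small <- gen_oesophageal_trace(tt, data.frame(time = 300, mass = 1.8),
                                 drop_rate = 0.10)
  expect_gte(nrow(detect_feeding_events(small$record)), 1)
  # non-uniform sampling is refused with the gap named
  bad <- data.frame(time = c(0:10, 20:30), temperature = 38)
  expect_error(detect_feeding_events(bad), "not uniformly sampled")
})

test_that("feeding detection is monotone in the rate threshold", {
  set.seed(7)
  tt <- seq(0, 4000, by = 2)
  for (rep in 1:20) {
    n_ing <- sample(3:8, 1)
    ing <- data.frame(time = sort(sample(seq(100, 3800, by = 200), n_ing)),
                      mass = runif(n_ing, 2, 25))
    tr <- gen_oesophageal_trace(tt, ing, drop_rate = runif(n_ing, 0.02, 0.15),
                                noise_sd = 0.005, seed = rep)
    counts <- vapply(c(0.02, 0.04, 0.06, 0.08, 0.12), function(thr) {
      nrow(detect_feeding_events(tr$record, rate_threshold = thr))
    }, 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("bout segmentation partitions dives by surface gaps", {
  # four identical 100 m dives with surface gaps [60, 4000, 60]
  D <- 2 * 100 / 1.3 + 12 # analytic dive duration: descent + hold + ascent
  gaps <- c(60, 4000, 60, 120)
  starts <- cumsum(c(0, (D + gaps)[-4]))
  plan2 <- dive_plan(starts, 100, post_surface = gaps)
  sim <- gen_dive_record(plan2, sampling_interval = 2, seed = 31)
  feats <- dive_features(sim$record, detect_dives(sim$record, min_depth = 3))
  bouts <- segment_bouts(feats, gap_threshold = 1800)
  expect_equal(nrow(bouts), 2)
  expect_equal(bouts$n_dives, c(2, 2))
  # all gaps below threshold: one bout
  one <- segment_bouts(feats, gap_threshold = 1e6)
  expect_equal(nrow(one), 1)
  expect_equal(one$n_dives, 4)
  # covariate set matches the bout-model design
  expect_true(all(c("n_events", "n_dives", "max_depth", "n_wiggles",
                    "ascent_rate", "descent_rate", "n_steps",
                    "surface_duration") %in% names(bouts)))
})

test_that("thermocline estimation finds the gradient maximum", {
  # 6 degC above 150 m, linear decline to 2 degC at 190 m: layer centre 170
  d <- seq(0, 250, by = 1)
  temp <- ifelse(d < 150, 6, ifelse(d <= 190, 6 - 4 * (d - 150) / 40, 2))
  est <- estimate_thermocline(data.frame(depth = d, temperature = temp))
  expect_equal(est$depth, 170, tolerance = 0.01) # layer midpoint
  # tanh profile centred at 120 m
  t2 <- 5 - 2 * tanh((d - 120) / 15)
  est2 <- estimate_thermocline(data.frame(depth = d, temperature = t2))
  expect_equal(est2$depth, 120, tolerance = 2) # within a bin width
  # isothermal: warning and NULL
  expect_warning(
    iso <- estimate_thermocline(data.frame(depth = d, temperature = rep(5, length(d)))),
    "isothermal")
  expect_null(iso)
  # shallow profile: warning, nothing returned
  expect_warning(
    sh <- estimate_thermocline(data.frame(depth = seq(0, 40, 2),
                                          temperature = seq(8, 4, length.out = 21))),
    "shallower")
  expect_null(sh)
  # invariance to adding a constant temperature offset
  est3 <- estimate_thermocline(data.frame(depth = d, temperature = t2 + 3.7))
  expect_equal(est3$depth, est2$depth)
})

test_that("phase feeding comparison matches exact enumeration", {
  r <- phase_feeding_comparison(c(1, 2, 3), c(4, 5, 6))
  expect_equal(unname(r$U), 0)
  expect_equal(r$p_value, 0.1)
  expect_equal(r$p_value, oracle_mw_exact_p(c(1, 2, 3), c(4, 5, 6)))
  # identical samples: uninformative
  expect_equal(phase_feeding_comparison(rep(2, 5), rep(2, 4))$p_value, 1)
  # a couple of random small-sample checks against full enumeration
  set.seed(12)
  for (i in 1:5) {
    a <- sample(seq(1, 99, 2), 6); b <- sample(seq(2, 100, 2), 7) # no ties
    expect_equal(phase_feeding_comparison(a, b)$p_value,
                 oracle_mw_exact_p(a, b), tolerance = 1e-8)
  }
})

test_that("front dives show the planted elevated feeding rate", {
  trip <- plan_foraging_trip(n_dives = 60, front_ratio = 2, seed = 41)
  prey_per_dive <- vapply(seq_len(nrow(trip$plan)), function(j) {
    sum(trip$ingestions$dive == j)
  }, 0)
  r <- phase_feeding_comparison(prey_per_dive[trip$phase == "front"],
                                prey_per_dive[trip$phase == "transit"])
  expect_lt(r$p_value, 0.05)
})
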