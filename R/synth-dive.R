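#' Build a dive plan with planted behavioural features
#'
#' A dive plan is the ground truth handed to [gen_dive_record()]: one row per
#' dive with the features the dive-signal detectors are later asked to
#' recover (maximal depth, wiggle and step counts, vertical rates, post-dive
#' surface interval).
#'
#' @param start numeric vector of dive start times (s).
#' @param max_depth maximal depth per dive (m, positive downward).
#' @param n_wiggles integer count of depth reversals planted in the bottom
#'   phase of each dive.
#' @param n_steps integer count of slow-speed plateaus planted in the descent.
#' @param descent_rate,ascent_rate vertical speeds (m s^-1); the field-typical
#'   value for king penguins is about 1.3 m s^-1.
#' @param bottom_hold minimum flat time at maximal depth (s).
#' @param post_surface surface interval after each dive (s).
#' @return a `data.frame` of class `dive_plan`.
#' @export
dive_plan <- function(start, max_depth, n_wiggles = 0L, n_steps = 0L,
                      descent_rate = 1.3, ascent_rate = 1.3,
                      bottom_hold = 40, post_surface = 60) {
  n <- length(start)
  plan <- data.frame(
    start = as.numeric(start),
    max_depth = rep_len(as.numeric(max_depth), n),
    n_wiggles = rep_len(as.integer(n_wiggles), n),
    n_steps = rep_len(as.integer(n_steps), n),
    descent_rate = rep_len(as.numeric(descent_rate), n),
    ascent_rate = rep_len(as.numeric(ascent_rate), n),
    bottom_hold = rep_len(as.numeric(bottom_hold), n),
    post_surface = rep_len(as.numeric(post_surface), n)
  )
  stop_if_not(all(plan$max_depth > 0), "max_depth must be positive")
  stop_if_not(all(plan$n_wiggles >= 0) && all(plan$n_steps >= 0),
              "wiggle/step counts must be non-negative")
  stop_if_not(all(plan$descent_rate > 0) && all(plan$ascent_rate > 0),
              "vertical rates must be positive")
  class(plan) <- c("dive_plan", "data.frame")
  plan
}

#' Draw a random foraging-trip dive plan with prey-ingestion truth
#'
#' Emulates a multi-day foraging trip: dive depths uniform over
#' `depth_range` (default the 50-306 m foraging-dive range), small random
#' wiggle/step counts, and per-dive prey ingestions placed inside the bottom
#' phase. Dives can be labelled `"transit"` or `"front"`; the mean number of
#' prey per dive at the front is `front_ratio` times the transit rate,
#' emulating the elevated capture rate at the polar front.
#'
#' @param n_dives number of dives.
#' @param depth_range numeric length-2, metres.
#' @param prey_rate_transit mean prey ingested per transit dive (Poisson).
#' @param front_ratio multiplier on the prey rate for front dives.
#' @param frac_front fraction of dives labelled `"front"` (the last dives of
#'   the trip, as in a commute-then-forage trip).
#' @param mean_mass mean prey mass (g); masses are gamma-distributed and
#'   floored at 1.8 g, the smallest prey the oesophageal sensor resolves.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return a list with elements `plan` (a [dive_plan()]), `ingestions`
#'   (data.frame: time, mass, dive), and `phase` (per-dive label).
#' @export
plan_foraging_trip <- function(n_dives = 60, depth_range = c(50, 306),
                               prey_rate_transit = 2, front_ratio = 2,
                               frac_front = 0.5, mean_mass = 12,
                               seed = 1) {
  set.seed(seed)
  depth <- stats::runif(n_dives, depth_range[1], depth_range[2])
  wig <- stats::rpois(n_dives, 3)
  stp <- stats::rpois(n_dives, 0.7)
  n_front <- round(frac_front * n_dives)
  phase <- c(rep("transit", n_dives - n_front), rep("front", n_front))
  surf <- stats::runif(n_dives, 60, 180)
  # lay dives head-to-tail: exact durations from the vertex geometry
  proto <- dive_plan(rep(0, n_dives), depth, wig, stp, post_surface = surf)
  dur <- vapply(seq_len(n_dives),
                function(j) dive_vertices(proto[j, ])$end, 0)
  start <- cumsum(c(0, dur[-n_dives] + surf[-n_dives]))
  plan <- dive_plan(start, depth, wig, stp, post_surface = surf)
  rate <- ifelse(phase == "front", prey_rate_transit * front_ratio, prey_rate_transit)
  n_prey <- stats::rpois(n_dives, rate)
  ing <- NULL
  geo <- dive_geometry(plan)
  for (j in seq_len(n_dives)) {
    if (n_prey[j] == 0) next
    tt <- sort(stats::runif(n_prey[j], geo$bottom_start[j] + 1, geo$bottom_end[j] - 1))
    mm <- pmax(1.8, stats::rgamma(n_prey[j], shape = 4, scale = mean_mass / 4))
    ing <- rbind(ing, data.frame(time = tt, mass = mm, dive = j))
  }
  if (is.null(ing)) ing <- data.frame(time = numeric(), mass = numeric(), dive = integer())
  list(plan = plan, ingestions = ing, phase = phase)
}

# Piecewise-linear vertex construction for one plan. Wiggles are planted in
# the bottom phase (excursion 15% of max depth, so depth never leaves the
# 80%-of-max bottom band); steps are slow plateaus (0.2 m/s for 20 s) planted
# in the upper three quarters of the descent, below 80% of max depth is
# avoided so steps stay inside the descent phase.
dive_vertices <- function(d) {
  wig_speed <- 1.0
  wig_amp <- 0.15 * d$max_depth
  step_speed <- 0.2
  step_dur <- 20
  t <- d$start
  vt <- t; vd <- 0
  push <- function(dt, depth) {
    t <<- t + dt
    vt <<- c(vt, t); vd <<- c(vd, depth)
  }
  # descent with planted steps at evenly spaced depths within [0, 0.75*max]
  step_depths <- if (d$n_steps > 0) {
    0.75 * d$max_depth * seq_len(d$n_steps) / (d$n_steps + 1)
  } else numeric()
  prev <- 0
  for (sd_ in step_depths) {
    push((sd_ - prev) / d$descent_rate, sd_)
    push(step_dur, sd_ + step_speed * step_dur)
    prev <- sd_ + step_speed * step_dur
  }
  push((d$max_depth - prev) / d$descent_rate, d$max_depth)
  bottom_start <- t
  # bottom: hold, then wiggles (up then back down), holds between; holds are
  # at least 12 s so adjacent wiggles remain separable at 5 s sampling
  hold <- max(12, d$bottom_hold / (d$n_wiggles + 1))
  push(hold, d$max_depth)
  if (d$n_wiggles > 0) {
    for (k in seq_len(d$n_wiggles)) {
      push(wig_amp / wig_speed, d$max_depth - wig_amp)
      push(wig_amp / wig_speed, d$max_depth)
      push(hold, d$max_depth)
    }
  }
  bottom_end <- t
  push(d$max_depth / d$ascent_rate, 0)
  end <- t
  push(d$post_surface, 0)
  list(t = vt, depth = vd, bottom_start = bottom_start,
       bottom_end = bottom_end, end = end)
}

# Bottom-phase windows and end times for every dive in a plan.
dive_geometry <- function(plan) {
  out <- lapply(seq_len(nrow(plan)), function(j) {
    v <- dive_vertices(plan[j, ])
    c(bottom_start = v$bottom_start, bottom_end = v$bottom_end, end = v$end)
  })
  as.data.frame(do.call(rbind, out))
}

#' Generate a sampled depth record realizing a dive plan
#'
#' Builds a piecewise-linear depth trace that realizes exactly the planted
#' dives, wiggles and steps of `plan`, then samples it on a uniform grid.
#'
#' @param plan a [dive_plan()].
#' @param sampling_interval sampling step in seconds; loggers of the kind
#'   emulated here sample every 1, 2 or 5 s.
#' @param seed integer seed (only used when `noise_sd > 0`).
#' @param noise_sd depth sensor noise s.d. (m), default 0.
#' @return a list of class `depth_record_sim`: `record` (data.frame `time`,
#'   `depth`), `truth` (the plan with realized bottom windows), and
#'   `sampling_interval`.
#' @export
gen_dive_record <- function(plan, sampling_interval = 2, seed = 1, noise_sd = 0) {
  stop_if_not(sampling_interval %in% c(1, 2, 5),
              "sampling_interval must be 1, 2 or 5 s")
  stop_if_not(inherits(plan, "dive_plan"), "plan must be a dive_plan")
  plan <- plan[order(plan$start), , drop = FALSE]
  verts <- lapply(seq_len(nrow(plan)), function(j) dive_vertices(plan[j, ]))
  ends <- vapply(verts, function(v) v$end, 0)
  if (nrow(plan) > 1) {
    overlap <- plan$start[-1] < ends[-length(ends)]
    stop_if_not(!any(overlap), "overlapping dives in plan (dive %d starts before dive %d ends)",
                which(overlap)[1] + 1, which(overlap)[1])
  }
  vt <- c(plan$start[1] - sampling_interval)
  vd <- c(0)
  for (v in verts) { vt <- c(vt, v$t); vd <- c(vd, v$depth) }
  # de-duplicate identical consecutive vertex times
  keep <- c(TRUE, diff(vt) > 0)
  vt <- vt[keep]; vd <- vd[keep]
  grid <- seq(0, max(vt), by = sampling_interval)
  depth <- stats::approx(vt, vd, xout = grid, rule = 2)$y
  if (noise_sd > 0) {
    set.seed(seed)
    depth <- pmax(0, depth + stats::rnorm(length(depth), 0, noise_sd))
  }
  truth <- plan
  geo <- dive_geometry(plan)
  truth$bottom_start <- geo$bottom_start
  truth$bottom_end <- geo$bottom_end
  truth$end <- geo$end
  structure(list(record = data.frame(time = grid, depth = depth),
                 truth = truth, sampling_interval = sampling_interval),
            class = "depth_record_sim")
}

#' Generate an oesophageal temperature trace with planted ingestion drops
#'
#' Each prey ingestion produces a temperature drop: a linear decline at
#' `drop_rate` from a warm baseline, followed by an exponential recovery.
#' Drop amplitude scales with prey mass, so the smallest detectable prey
#' (1.8 g by default parameterization) sits just above a typical amplitude
#' cut-off. The drop rate parameter lets a simulation straddle the
#' 0.06 degC/s feeding-event detection rule.
#'
#' @param times numeric vector of sample times (s), uniform grid, or a
#'   `depth_record_sim` whose time grid is reused.
#' @param ingestions data.frame with columns `time` (s) and `mass` (g).
#' @param baseline stomach/oesophagus baseline temperature (degC).
#' @param drop_rate rate of temperature decrease during a drop (degC s^-1);
#'   recycled over ingestions.
#' @param amp_per_g drop amplitude per gram of prey (degC g^-1).
#' @param recovery_tau exponential recovery time constant (s).
#' @param noise_sd sensor noise s.d. (degC).
#' @param seed integer seed (noise only).
#' @return list of class `temperature_record_sim`: `record` (data.frame
#'   `time`, `temperature`), `truth` (per-event onset, rate, amplitude),
#'   `resolution` (degC).
#' @export
gen_oesophageal_trace <- function(times, ingestions,
                                  baseline = 38, drop_rate = 0.10,
                                  amp_per_g = 0.06, recovery_tau = 60,
                                  noise_sd = 0, seed = 1) {
  if (inherits(times, "depth_record_sim")) times <- times$record$time
  stop_if_not(is.numeric(times) && length(times) >= 2, "need a numeric time grid")
  if (nrow(ingestions) > 0) {
    stop_if_not(all(ingestions$mass > 0), "prey mass must be positive")
  }
  rates <- rep_len(drop_rate, max(1L, nrow(ingestions)))
  temp <- rep(baseline, length(times))
  truth <- NULL
  if (nrow(ingestions) > 0) {
    for (i in seq_len(nrow(ingestions))) {
      amp <- amp_per_g * ingestions$mass[i]
      r <- rates[i]
      dur <- amp / r
      t0 <- ingestions$time[i]
      rel <- times - t0
      f <- ifelse(rel < 0, 0,
                  ifelse(rel < dur, r * rel, amp * exp(-(rel - dur) / recovery_tau)))
      temp <- temp - f
      truth <- rbind(truth, data.frame(onset = t0, rate = r, amplitude = amp,
                                       mass = ingestions$mass[i]))
    }
  }
  if (noise_sd > 0) {
    set.seed(seed)
    temp <- temp + stats::rnorm(length(temp), 0, noise_sd)
  }
  structure(list(record = data.frame(time = times, temperature = temp),
                 truth = truth %||% data.frame(onset = numeric(), rate = numeric(),
                                               amplitude = numeric(), mass = numeric()),
                 resolution = 0.01),
            class = "temperature_record_sim")
}
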