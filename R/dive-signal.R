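# Dive, wiggle, step, bout and thermocline extraction from biologging
# records. Depth is positive downward; vertical speed is depth change per
# second, positive while descending, so a wiggle (brief depth reversal) is a
# negative excursion of vertical speed between non-negative stretches.

as_depth_record <- function(rec) {
  if (inherits(rec, "depth_record_sim")) rec <- rec$record
  stop_if_not(all(c("time", "depth") %in% names(rec)),
              "depth record needs columns time, depth")
  stop_if_not(all(rec$depth >= 0), "negative depths: apply zero-offset correction first")
  rec
}

#' Detect dives in a depth record
#'
#' A dive is a maximal submerged interval whose maximal depth reaches
#' `min_depth`. Phases: descent from the surface to the first sample in the
#' bottom band (depth >= 80% of maximal depth), bottom while within the
#' band, ascent from the last bottom sample back to the surface. Descent and
#' ascent rates are the phase depth span divided by the phase duration.
#'
#' @param rec data.frame (`time`, `depth`) or a `depth_record_sim`.
#' @param min_depth minimal maximal depth (m) for a dive to be retained;
#'   the default 3 m keeps all true dives, while foraging-dive analyses
#'   typically refilter at 50 m (the floor of the foraging depth range).
#' @param surface_threshold depth (m) above which the bird counts as
#'   submerged.
#' @param bottom_frac bottom band as a fraction of maximal depth.
#' @return data.frame of class `dive_table`, one row per dive: sample
#'   indices, times, maximal depth, phase boundaries, rates, duration and
#'   post-dive surface interval.
#' @export
detect_dives <- function(rec, min_depth = 3, surface_threshold = 0.5,
                         bottom_frac = 0.8) {
  stop_if_not(min_depth > 0, "min_depth must be positive")
  rec <- as_depth_record(rec)
  empty <- data.frame(start_idx = integer(), end_idx = integer(),
                      start_time = numeric(), end_time = numeric(),
                      max_depth = numeric(), duration = numeric(),
                      bottom_start_idx = integer(), bottom_end_idx = integer(),
                      descent_rate = numeric(), ascent_rate = numeric(),
                      bottom_duration = numeric(), post_dive_surface = numeric())
  if (nrow(rec) == 0) return(structure(empty, class = c("dive_table", "data.frame")))
  sub <- rec$depth > surface_threshold
  r <- rle(sub)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- which(r$values)
  rows <- list()
  for (s in segs) {
    i0 <- starts[s]; i1 <- ends[s]
    md <- max(rec$depth[i0:i1])
    if (md < min_depth) next
    band <- which(rec$depth[i0:i1] >= bottom_frac * md) + i0 - 1
    b0 <- band[1]; b1 <- band[length(band)]
    desc_dur <- rec$time[b0] - rec$time[i0]
    asc_dur <- rec$time[i1] - rec$time[b1]
    rows[[length(rows) + 1]] <- data.frame(
      start_idx = i0, end_idx = i1,
      start_time = rec$time[i0], end_time = rec$time[i1],
      max_depth = md, duration = rec$time[i1] - rec$time[i0],
      bottom_start_idx = b0, bottom_end_idx = b1,
      descent_rate = if (desc_dur > 0) (rec$depth[b0] - rec$depth[i0]) / desc_dur else NA_real_,
      ascent_rate = if (asc_dur > 0) (rec$depth[b1] - rec$depth[i1]) / asc_dur else NA_real_,
      bottom_duration = rec$time[b1] - rec$time[b0],
      post_dive_surface = NA_real_)
  }
  if (length(rows) == 0) return(structure(empty, class = c("dive_table", "data.frame")))
  dives <- do.call(rbind, rows)
  n <- nrow(dives)
  nxt <- c(dives$start_time[-1], rec$time[nrow(rec)])
  dives$post_dive_surface <- nxt - dives$end_time
  structure(dives, class = c("dive_table", "data.frame"))
}

# vertical speed over sample intervals (positive descending)
vertical_speed <- function(rec) {
  diff(rec$depth) / diff(rec$time)
}

#' Count wiggles in a dive
#'
#' A wiggle is a brief depth reversal against the prevailing downward
#' motion: a maximal run of negative vertical speed bracketed by
#' non-negative speed, counted within the descent and bottom phases (the
#' ascent, where negative speed is the prevailing direction, is excluded).
#' Overlapping sample triples belonging to one reversal are merged: each
#' down-crossing/up-crossing pair of the vertical speed through zero counts
#' once.
#'
#' @param dive one row of a `dive_table`.
#' @param rec the depth record the dive was detected in.
#' @return integer wiggle count.
#' @export
count_wiggles <- function(dive, rec) {
  rec <- as_depth_record(rec)
  i0 <- dive$start_idx; b1 <- dive$bottom_end_idx
  if (b1 - i0 < 2) return(0L)
  v <- vertical_speed(rec[i0:b1, ])
  neg <- v < 0
  if (!any(neg)) return(0L)
  r <- rle(neg)
  n_runs <- sum(r$values)
  # a trailing negative run has no return to >= 0 within descent+bottom:
  # it is the start of the ascent, not a wiggle
  if (r$values[length(r$values)]) n_runs <- n_runs - 1L
  as.integer(n_runs)
}

#' Count steps in a dive
#'
#' A step is a maximal period within the descent or ascent during which the
#' magnitude of the vertical speed falls to `speed_threshold` or below
#' without reversing sign (depth keeps moving in the phase direction, or
#' pauses, but does not reverse).
#'
#' @param dive one row of a `dive_table`.
#' @param rec the depth record.
#' @param speed_threshold m s^-1; default 0.35.
#' @return integer step count.
#' @export
count_steps <- function(dive, rec, speed_threshold = 0.35) {
  stop_if_not(speed_threshold > 0, "speed_threshold must be positive")
  rec <- as_depth_record(rec)
  count_phase <- function(i0, i1, sign_dir) {
    if (i1 - i0 < 1) return(0L)
    v <- vertical_speed(rec[i0:i1, ]) * sign_dir
    instep <- v >= 0 & v <= speed_threshold
    if (!any(instep)) return(0L)
    r <- rle(instep)
    sum(r$values)
  }
  count_phase(dive$start_idx, dive$bottom_start_idx, 1) +
    count_phase(dive$bottom_end_idx, dive$end_idx, -1)
}

#' Per-dive feature table
#'
#' Augments a `dive_table` with wiggle and step counts.
#'
#' @param rec depth record.
#' @param dives `dive_table` from [detect_dives()].
#' @param speed_threshold step speed threshold (m s^-1).
#' @return the `dive_table` with columns `n_wiggles`, `n_steps`.
#' @export
dive_features <- function(rec, dives, speed_threshold = 0.35) {
  rec <- as_depth_record(rec)
  dives$n_wiggles <- vapply(seq_len(nrow(dives)), function(j) {
    count_wiggles(dives[j, ], rec)
  }, 0L)
  dives$n_steps <- vapply(seq_len(nrow(dives)), function(j) {
    count_steps(dives[j, ], rec, speed_threshold)
  }, 0L)
  dives
}

# Threshold-independent drop-episode segmentation of a temperature trace.
# An episode starts when temperature falls min_amplitude below the running
# baseline (the last local maximum) and ends when it has recovered
# recovery_frac of the drop amplitude.
find_drop_episodes <- function(rec, min_amplitude = 0.1, recovery_frac = 0.8) {
  tt <- rec$time; Tv <- rec$temperature
  n <- length(Tv)
  dt <- uniform_dt(tt)
  episodes <- list()
  base_i <- 1L
  i <- 2L
  while (i <= n) {
    if (Tv[i] >= Tv[base_i]) {
      base_i <- i
    } else if (Tv[base_i] - Tv[i] >= min_amplitude) {
      onset <- base_i
      min_i <- i
      j <- i
      while (j <= n) {
        if (Tv[j] < Tv[min_i]) min_i <- j
        amp <- Tv[onset] - Tv[min_i]
        target <- Tv[onset] - (1 - recovery_frac) * amp
        if (Tv[j] >= target && j > min_i) break
        j <- j + 1L
      }
      j <- min(j, n)
      seg <- Tv[onset:min_i]
      max_rate <- if (min_i > onset) max(-diff(seg)) / dt else 0
      episodes[[length(episodes) + 1]] <- data.frame(
        onset = tt[onset], end = tt[j],
        amplitude = Tv[onset] - Tv[min_i],
        duration = tt[j] - tt[onset],
        max_drop_rate = max_rate)
      base_i <- j
      i <- j
    }
    i <- i + 1L
  }
  if (length(episodes) == 0) {
    return(data.frame(onset = numeric(), end = numeric(), amplitude = numeric(),
                      duration = numeric(), max_drop_rate = numeric()))
  }
  do.call(rbind, episodes)
}

#' Detect feeding events in an oesophageal temperature record
#'
#' Ingestion of cold prey produces a sharp temperature drop. The record is
#' first segmented into drop episodes (a fall of at least `min_amplitude`
#' below the running baseline, ended once `recovery_frac` of the drop has
#' been recovered); an episode is a feeding event when its maximum
#' descending rate (finite difference over adjacent samples) reaches
#' `rate_threshold`, its amplitude reaches `min_amplitude` and its duration
#' does not exceed `max_duration`. The 0.06 degC/s default rate criterion is
#' the calibrated feeding/non-feeding discrimination threshold for
#' oesophageal sensors.
#'
#' @param rec data.frame (`time`, `temperature`) or a
#'   `temperature_record_sim`; must be uniformly sampled.
#' @param rate_threshold degC s^-1 (default 0.06).
#' @param min_amplitude degC (default 0.1).
#' @param max_duration s (default 300).
#' @param recovery_frac fraction of the drop that must be recovered before
#'   a new episode can begin.
#' @return data.frame of class `feeding_events`: `onset`, `drop_rate`,
#'   `amplitude`, `duration`.
#' @export
detect_feeding_events <- function(rec, rate_threshold = 0.06,
                                  min_amplitude = 0.1, max_duration = 300,
                                  recovery_frac = 0.8) {
  if (inherits(rec, "temperature_record_sim")) rec <- rec$record
  stop_if_not(all(c("time", "temperature") %in% names(rec)),
              "temperature record needs columns time, temperature")
  uniform_dt(rec$time)
  ep <- find_drop_episodes(rec, min_amplitude, recovery_frac)
  keep <- ep$max_drop_rate >= rate_threshold - 1e-12 &
    ep$amplitude >= min_amplitude - 1e-12 &
    ep$duration <= max_duration
  out <- data.frame(onset = ep$onset[keep], drop_rate = ep$max_drop_rate[keep],
                    amplitude = ep$amplitude[keep], duration = ep$duration[keep])
  structure(out, class = c("feeding_events", "data.frame"))
}

#' Segment dives into diving bouts and build the bout covariate table
#'
#' Consecutive dives whose post-dive surface interval is below
#' `gap_threshold` share a bout. Bout covariates are per-dive means (the
#' number of dives excepted), matching the covariate set of the bout-scale
#' prey-capture model: number of dives, maximal depth, wiggles, ascent and
#' descent rates, steps, and pre-dive surface duration. If feeding events
#' are supplied, events whose onset falls within a bout are counted as the
#' bout response.
#'
#' @param dives a `dive_table` with `n_wiggles`/`n_steps` columns (see
#'   [dive_features()]).
#' @param gap_threshold bout-ending surface interval (s); the default
#'   1800 s is a configuration choice, not a measured constant.
#' @param events optional `feeding_events`.
#' @return data.frame of class `bout_table`: `n_events` (NA without
#'   events), `n_dives`, `max_depth`, `n_wiggles`, `ascent_rate`,
#'   `descent_rate`, `n_steps`, `surface_duration`, `start_time`,
#'   `end_time`.
#' @export
segment_bouts <- function(dives, gap_threshold = 1800, events = NULL) {
  stop_if_not(nrow(dives) > 0, "no dives")
  stop_if_not(!is.unsorted(dives$start_time), "dives must be time-ordered")
  stop_if_not(all(c("n_wiggles", "n_steps") %in% names(dives)),
              "run dive_features() first")
  gap_before <- c(Inf, dives$post_dive_surface[-nrow(dives)])
  bout_id <- cumsum(gap_before >= gap_threshold)
  rows <- lapply(split(seq_len(nrow(dives)), bout_id), function(ix) {
    d <- dives[ix, ]
    n_ev <- if (is.null(events)) NA_integer_ else {
      sum(events$onset >= d$start_time[1] &
            events$onset <= d$end_time[nrow(d)])
    }
    data.frame(n_events = n_ev,
               n_dives = nrow(d),
               max_depth = mean(d$max_depth),
               n_wiggles = mean(d$n_wiggles),
               ascent_rate = mean(d$ascent_rate, na.rm = TRUE),
               descent_rate = mean(d$descent_rate, na.rm = TRUE),
               n_steps = mean(d$n_steps),
               surface_duration = mean(d$post_dive_surface),
               start_time = d$start_time[1],
               end_time = d$end_time[nrow(d)])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("bout_table", "data.frame"))
}

#' Estimate thermocline depth from depth-temperature profiles
#'
#' Profiles are median-binned onto a regular depth grid (2 m default),
#' lightly smoothed with a running mean, and the thermocline is the depth of
#' the maximum magnitude of the vertical temperature gradient (central
#' differences). When the maximal gradient extends over a layer (within
#' numerical tolerance), the layer midpoint is reported.
#'
#' @param profiles data.frame (`depth`, `temperature`) or a list of such
#'   data.frames (e.g. one per dive).
#' @param bin_width depth bin (m), default 2.
#' @param smooth_k running-mean window (bins, odd).
#' @param min_gradient smallest gradient magnitude (degC m^-1) accepted as a
#'   thermocline; near-isothermal profiles return `NULL`.
#' @return list of class `thermocline_estimate` (`depth` m, `gradient`
#'   degC m^-1, `profile` the binned profile), or `NULL` with a warning.
#' @export
estimate_thermocline <- function(profiles, bin_width = 2, smooth_k = 5,
                                 min_gradient = 0.005) {
  if (is.data.frame(profiles)) profiles <- list(profiles)
  all_d <- unlist(lapply(profiles, `[[`, "depth"))
  all_t <- unlist(lapply(profiles, `[[`, "temperature"))
  stop_if_not(length(all_d) >= 5, "need at least 5 depth samples")
  if (max(all_d) < 50) {
    warning("profile shallower than 50 m: no thermocline estimate")
    return(NULL)
  }
  stop_if_not(diff(range(all_d)) >= 100, "profiles must span at least 100 m")
  grid <- seq(floor(min(all_d)), ceiling(max(all_d)), by = bin_width)
  bin <- findInterval(all_d, grid, rightmost.closed = TRUE)
  med <- tapply(all_t, bin, stats::median)
  depth <- grid[as.integer(names(med))] + bin_width / 2
  temp <- as.numeric(med)
  ok <- stats::complete.cases(depth, temp)
  depth <- depth[ok]; temp <- temp[ok]
  stop_if_not(length(depth) >= 5, "too few occupied depth bins")
  # running-mean smoothing
  k <- max(1L, smooth_k - (1 - smooth_k %% 2)) # force odd
  if (k > 1) {
    temp <- stats::filter(temp, rep(1 / k, k), sides = 2)
    keep <- !is.na(temp)
    depth <- depth[keep]; temp <- as.numeric(temp[keep])
  }
  n <- length(temp)
  stop_if_not(n >= 3, "too few bins after smoothing")
  g <- (temp[3:n] - temp[1:(n - 2)]) / (depth[3:n] - depth[1:(n - 2)])
  gd <- depth[2:(n - 1)]
  ag <- abs(g)
  gmax <- max(ag)
  if (gmax < min_gradient) {
    warning("profile is (near-)isothermal: no gradient maximum")
    return(NULL)
  }
  layer <- which(ag >= gmax * (1 - 1e-6))
  structure(list(depth = mean(gd[layer]), gradient = g[layer[1]],
                 profile = data.frame(depth = depth, temperature = temp)),
            class = "thermocline_estimate")
}

#' Rank-sum comparison of feeding rates between trip phases
#'
#' Two-sided Mann-Whitney / Wilcoxon rank-sum test comparing per-unit
#' feeding rates (e.g. prey per dive) between the commuting (transit) phase
#' and the time spent at the polar front. Exact for small samples without
#' ties; normal approximation with tie correction otherwise. When every
#' value is tied the comparison is uninformative and p = 1.
#'
#' @param front,transit numeric samples.
#' @return list: `U` (Mann-Whitney statistic for `front` vs `transit`),
#'   `p_value`, `n_front`, `n_transit`, `method`.
#' @export
phase_feeding_comparison <- function(front, transit) {
  stop_if_not(length(front) > 0 && length(transit) > 0,
              "both samples must be non-empty")
  if (length(unique(c(front, transit))) == 1) {
    return(list(U = length(front) * length(transit) / 2, p_value = 1,
                n_front = length(front), n_transit = length(transit),
                method = "all values tied"))
  }
  wt <- suppressWarnings(stats::wilcox.test(front, transit, exact = NULL))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(U = unname(wt$statistic), p_value = p,
       n_front = length(front), n_transit = length(transit),
       method = wt$method)
}
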