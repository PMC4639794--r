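#' Simulate a stochastic Gompertz count series with observation error
#'
#' Process model on log abundance \eqn{x_t = \ln N_t}:
#' \deqn{x_{t+1} = x_t + r - b x_t + c z_t + \epsilon_t, \quad
#'       \epsilon_t \sim N(0, \tau^2)}
#' with observed log abundance \eqn{y_t = x_t + \eta_t},
#' \eqn{\eta_t \sim N(0, \sigma^2)}. Here \eqn{r} is the growth rate at
#' \eqn{N = 1}, \eqn{b} the strength of density dependence (so \eqn{1 - b}
#' is the lag-1 autocorrelation of log abundance), and \eqn{c} the effect of
#' a standardized environmental covariate \eqn{z_t}. The stationary mean is
#' \eqn{x^* = (r + c \bar z)/b} when \eqn{b > 0}.
#'
#' @param n_years series length (>= 3).
#' @param r growth rate at N = 1 (default the posterior-mean scale of the
#'   motivating king penguin analysis, 0.101).
#' @param b density-dependence strength (default 0.008).
#' @param c_cov covariate effect on the standardized covariate scale
#'   (default -0.067, a negative front/dipole effect).
#' @param tau process-error s.d. (default 0.099).
#' @param sigma observation-error s.d. (default 0.113).
#' @param z covariate series (length `n_years`); standardized internally
#'   unless constant. `NULL` draws a standard-normal series.
#' @param x1 initial log abundance; default the stationary point
#'   \eqn{r/b} (about 12.6, i.e. ~3e5 breeding pairs) or `y`-scale 10 when
#'   `b = 0`.
#' @param seed integer seed.
#' @return list of class `gompertz_sim` with `series` (data.frame `year`,
#'   `x`, `y`, `z`, `N = exp(y)`) and `truth` (the parameters).
#' @export
gen_gompertz_series <- function(n_years = 30, r = 0.101, b = 0.008,
                                c_cov = -0.067, tau = 0.099, sigma = 0.113,
                                z = NULL, x1 = NULL, seed = 1) {
  stop_if_not(n_years >= 3, "n_years must be >= 3")
  stop_if_not(tau >= 0 && sigma >= 0, "tau and sigma must be non-negative")
  set.seed(seed)
  if (is.null(z)) z <- stats::rnorm(n_years)
  stop_if_not(length(z) == n_years, "z must have length n_years")
  if (stats::sd(z) > 0) z <- as.numeric(scale(z))
  if (is.null(x1)) x1 <- if (b > 0) r / b else 10
  x <- numeric(n_years)
  x[1] <- x1
  eps <- stats::rnorm(n_years - 1, 0, tau)
  for (t in seq_len(n_years - 1)) {
    x[t + 1] <- x[t] + r - b * x[t] + c_cov * z[t] + eps[t]
  }
  y <- x + stats::rnorm(n_years, 0, sigma)
  structure(list(
    series = data.frame(year = seq_len(n_years), x = x, y = y, z = z,
                        N = exp(y)),
    truth = list(r = r, b = b, c = c_cov, tau = tau, sigma = sigma, x1 = x1)
  ), class = "gompertz_sim")
}

#' Generate colony count tables with missing cells
#'
#' Counts follow a multiplicative colony-by-year model:
#' `lambda[colony, year] = exp(mu + colony effect + year effect)`, with
#' Poisson (or negative-binomial, if `theta` is finite) observation noise.
#' Year effects follow a random walk, emulating slow shared population
#' change across colonies. A fixed fraction of cells is masked at random
#' (every colony and year is kept observed at least once); the unmasked
#' truth is retained so imputation error can be measured. The motivating
#' survey had 4 colonies over 30 years with 43.9% of cells missing
#' (65 observed colony-years).
#'
#' @param n_colonies,n_years table dimensions.
#' @param mu overall log mean count.
#' @param colony_sd s.d. of colony effects (log scale).
#' @param year_sd random-walk step s.d. of year effects (log scale).
#' @param missing_frac fraction of cells masked, in `[0, 1)`.
#' @param theta negative-binomial size; `Inf` (default) gives Poisson counts.
#' @param seed integer seed.
#' @return list of class `colony_count_sim`: `table` (long data.frame
#'   `colony`, `year`, `count` with `NA` for masked cells), `truth`
#'   (complete counts and expected values), `masked` (logical vector).
#' @export
gen_colony_counts <- function(n_colonies = 4, n_years = 30, mu = 8,
                              colony_sd = 0.8, year_sd = 0.05,
                              missing_frac = 0.439, theta = Inf, seed = 1) {
  stop_if_not(missing_frac >= 0 && missing_frac < 1,
              "missing_frac must be in [0, 1)")
  set.seed(seed)
  col_eff <- stats::rnorm(n_colonies, 0, colony_sd)
  year_eff <- cumsum(stats::rnorm(n_years, 0, year_sd))
  year_eff <- year_eff - mean(year_eff)
  lambda <- exp(mu + outer(col_eff, year_eff, "+"))
  counts <- if (is.finite(theta)) {
    matrix(stats::rnbinom(length(lambda), size = theta, mu = lambda),
           n_colonies, n_years)
  } else {
    matrix(stats::rpois(length(lambda), lambda), n_colonies, n_years)
  }
  n_cells <- n_colonies * n_years
  n_mask <- round(missing_frac * n_cells)
  # mask cells uniformly at random, re-drawing while a colony or year would
  # lose its last observation
  ok <- FALSE
  for (attempt in 1:200) {
    mask_idx <- sample.int(n_cells, n_mask)
    masked <- rep(FALSE, n_cells)
    masked[mask_idx] <- TRUE
    mm <- matrix(masked, n_colonies, n_years)
    if (all(rowSums(!mm) > 0) && all(colSums(!mm) > 0)) { ok <- TRUE; break }
  }
  stop_if_not(ok, "could not mask %.1f%% of cells while keeping every colony and year observed",
              100 * missing_frac)
  tab <- data.frame(
    colony = factor(rep(seq_len(n_colonies), n_years)),
    year = rep(seq_len(n_years), each = n_colonies),
    count = as.vector(counts)
  )
  tab$count[masked] <- NA_integer_
  structure(list(table = tab,
                 truth = list(counts = counts, lambda = lambda,
                              colony_effects = col_eff, year_effects = year_eff),
                 masked = masked),
            class = "colony_count_sim")
}

#' Generate bout-level covariates and negative-binomial feeding counts
#'
#' Draws the covariate set used in the bout-scale prey-capture model
#' (log number of dives and its square, maximal depth, wiggles, ascent and
#' descent rates, steps, surface duration), standardizes them internally,
#' and simulates counts from a negative-binomial regression with log link:
#' `count ~ NB(mean = exp(X beta), size = theta)`. The default `beta` is the
#' averaged-coefficient vector of the motivating analysis (intercept 3.13,
#' log n dives 1.45, its square -0.25, max depth -0.12, wiggles 0.32,
#' ascent -0.03, descent 0.47, steps -0.11, surface -0.25), used here as
#' simulation truth. The default size, 36 + 38 bouts, mirrors the original
#' fit/validation split.
#'
#' @param n_bouts number of bouts (default 74 = 36 fit + 38 validation).
#' @param beta named coefficient vector on the standardized scale; names must
#'   be `intercept` plus a subset of the covariate names.
#' @param theta negative-binomial dispersion (size) parameter, > 0.
#' @param seed integer seed.
#' @return list of class `bout_table_sim`: `table` (a `bout_table`:
#'   response `n_events` plus raw covariates), `truth` (beta, theta, the
#'   standardized design).
#' @export
gen_bout_table <- function(n_bouts = 74,
                           beta = c(intercept = 3.13, log_n_dives = 1.45,
                                    log_n_dives_sq = -0.25, max_depth = -0.12,
                                    n_wiggles = 0.32, ascent_rate = -0.03,
                                    descent_rate = 0.47, n_steps = -0.11,
                                    surface_duration = -0.25),
                           theta = 2, seed = 1) {
  stop_if_not(theta > 0, "theta must be positive")
  set.seed(seed)
  n_dives <- pmax(2, stats::rpois(n_bouts, 12))
  raw <- data.frame(
    n_dives = n_dives,
    max_depth = stats::runif(n_bouts, 50, 306),
    n_wiggles = stats::rpois(n_bouts, 30),
    ascent_rate = stats::rnorm(n_bouts, 1.3, 0.15),
    descent_rate = stats::rnorm(n_bouts, 1.3, 0.15),
    n_steps = stats::rpois(n_bouts, 4),
    surface_duration = stats::rexp(n_bouts, 1 / 120)
  )
  des <- bout_design(raw)
  bnames <- names(beta)
  stop_if_not(!is.null(bnames) && "intercept" %in% bnames,
              "beta must be named and include 'intercept'")
  extra <- setdiff(bnames, c("intercept", colnames(des$z)))
  stop_if_not(length(extra) == 0, "unknown covariates in beta: %s",
              paste(extra, collapse = ", "))
  eta <- rep(beta[["intercept"]], n_bouts)
  for (nm in setdiff(bnames, "intercept")) eta <- eta + beta[[nm]] * des$z[, nm]
  mu <- exp(eta)
  counts <- if (is.finite(theta)) {
    stats::rnbinom(n_bouts, size = theta, mu = mu)
  } else {
    stats::rpois(n_bouts, mu)
  }
  tab <- cbind(data.frame(n_events = counts), raw)
  class(tab) <- c("bout_table", "data.frame")
  structure(list(table = tab,
                 truth = list(beta = beta, theta = theta, design = des, mu = mu)),
            class = "bout_table_sim")
}
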