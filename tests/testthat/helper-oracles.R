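# Independent brute-force oracles used to check the package detectors and
# statistics against their definitions.

# Definitional wiggle scan: within [i0, i1], vertical speed passing from
# >= 0 to < 0 and back to >= 0 counts one wiggle per down/up crossing pair.
oracle_wiggles <- function(depth, time, i0, i1) {
  n_w <- 0L
  in_neg <- FALSE
  for (i in i0:(i1 - 1)) {
    v <- (depth[i + 1] - depth[i]) / (time[i + 1] - time[i])
    if (!in_neg && v < 0) {
      in_neg <- TRUE
    } else if (in_neg && v >= 0) {
      n_w <- n_w + 1L
      in_neg <- FALSE
    }
  }
  n_w
}

# Definitional step scan over one phase: maximal periods where speed in the
# phase direction lies in [0, thr].
oracle_steps_phase <- function(depth, time, i0, i1, thr, dir) {
  if (i1 - i0 < 1) return(0L)
  n_s <- 0L
  in_step <- FALSE
  for (i in i0:(i1 - 1)) {
    v <- dir * (depth[i + 1] - depth[i]) / (time[i + 1] - time[i])
    if (v >= 0 && v <= thr) {
      if (!in_step) n_s <- n_s + 1L
      in_step <- TRUE
    } else {
      in_step <- FALSE
    }
  }
  n_s
}

# O(n^2) loop-based concordance index.
oracle_c_index <- function(obs, pred) {
  conc <- disc <- tied <- 0
  n <- length(obs)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (obs[i] == obs[j]) next
      s <- sign(obs[i] - obs[j]) * sign(pred[i] - pred[j])
      if (s > 0) conc <- conc + 1
      else if (s < 0) disc <- disc + 1
      else tied <- tied + 1
    }
  }
  (conc + 0.5 * tied) / (conc + disc + tied)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
oracle_mw_exact_p <- function(x, y) {
  vals <- c(x, y)
  n1 <- length(x)
  combs <- utils::combn(length(vals), n1)
  u_of <- function(ix) {
    a <- vals[ix]; b <- vals[-ix]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(combs, 2, u_of)
  mu <- length(x) * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Independent plain-R Gibbs sampler for the Gompertz autoregression with
# known states (the sigma = 0 reduction): conjugate normal update for
# (r, b, c), truncated inverse-gamma for tau^2.
oracle_gompertz_regression <- function(x, z, n_iter = 20000, n_burn = 2000,
                                       r_mean = 0.10, r_sd = 0.02,
                                       bc_sd = 10, sd_max = 3) {
  T_len <- length(x)
  d <- diff(x)
  X <- cbind(1, -x[-T_len], z[-T_len])
  P0 <- diag(c(1 / r_sd^2, 1 / bc_sd^2, 1 / bc_sd^2))
  m0 <- c(r_mean, 0, 0)
  tau2 <- 0.01
  out <- matrix(NA_real_, n_iter, 4)
  for (it in seq_len(n_iter + n_burn)) {
    A <- crossprod(X) / tau2 + P0
    V <- solve(A)
    mu <- V %*% (crossprod(X, d) / tau2 + P0 %*% m0)
    beta <- as.numeric(mu + t(chol(V)) %*% rnorm(3))
    ss <- sum((d - X %*% beta)^2)
    shape <- (length(d) - 1) / 2
    lo <- pgamma(1 / sd_max^2, shape, rate = ss / 2)
    u <- qgamma(runif(1, lo, 1), shape, rate = ss / 2)
    tau2 <- 1 / u
    if (it > n_burn) out[it - n_burn, ] <- c(beta, sqrt(tau2))
  }
  colnames(out) <- c("r", "b", "c", "tau")
  out
}

# Random jagged depth trace for definitional scan tests: bounded random walk
# with occasional plateaus, always non-negative.
random_depth_trace <- function(n, dt = 2) {
  steps <- rnorm(n - 1, 0, 3)
  steps[runif(n - 1) < 0.2] <- 0
  depth <- abs(cumsum(c(20, steps)))
  data.frame(time = seq(0, by = dt, length.out = n), depth = depth)
}

published_gompertz_means <- list(r = 0.101, b = 0.008, c = -0.067, tau = 0.099,
                     sigma = 0.113)

published_bout_coefs <- c("(Intercept)" = 3.13, log_n_dives = 1.45,
                  log_n_dives_sq = -0.25, max_depth = -0.12,
                  n_wiggles = 0.32, ascent_rate = -0.03,
                  descent_rate = 0.47, n_steps = -0.11,
                  surface_duration = -0.25)
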