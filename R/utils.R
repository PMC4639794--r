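# Internal helpers shared across modules.

# Meridian arc length used to convert latitude displacement to kilometres.
KM_PER_DEG_LAT <- 111.2

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}

#' Check that a time axis is uniformly sampled
#'
#' @param t numeric vector of timestamps (seconds), strictly increasing.
#' @param tol relative tolerance on the step.
#' @return the common sampling interval (seconds).
#' @keywords internal
uniform_dt <- function(t, tol = 1e-6) {
  stop_if_not(length(t) >= 2, "need at least 2 timestamps")
  d <- diff(t)
  stop_if_not(all(d > 0), "timestamps must be strictly increasing")
  dt <- stats::median(d)
  bad <- which(abs(d - dt) > tol * dt)
  if (length(bad)) {
    stop(sprintf(
      "record is not uniformly sampled: gap of %.6g s at t = %.6g (expected %.6g s)",
      d[bad[1]], t[bad[1]], dt
    ), call. = FALSE)
  }
  dt
}

# Standardize columns to zero mean / unit sd; returns matrix plus the
# centering/scaling used (so validation rows can reuse fit-row parameters).
standardize_cols <- function(x, center = NULL, scale = NULL) {
  x <- as.matrix(x)
  if (is.null(center)) center <- colMeans(x)
  if (is.null(scale)) {
    scale <- apply(x, 2, stats::sd)
    scale[scale == 0] <- 1
  }
  z <- sweep(sweep(x, 2, center, "-"), 2, scale, "/")
  list(z = z, center = center, scale = scale)
}

# Shortest interval containing `prob` posterior mass.
hpd_interval <- function(draws, prob = 0.95) {
  x <- sort(draws[is.finite(draws)])
  n <- length(x)
  stop_if_not(n >= 10, "too few draws for an HPD interval")
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[(m + 1):n] - x[1:(n - m)]
  i <- which.min(widths)
  c(lower = x[i], upper = x[i + m])
}

# Split-chain potential scale reduction factor (Gelman-Rubin).
split_rhat <- function(draws_by_chain) {
  halves <- list()
  for (ch in draws_by_chain) {
    n <- length(ch)
    h <- floor(n / 2)
    halves[[length(halves) + 1]] <- ch[1:h]
    halves[[length(halves) + 1]] <- ch[(h + 1):(2 * h)]
  }
  m <- length(halves)
  n <- length(halves[[1]])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}
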