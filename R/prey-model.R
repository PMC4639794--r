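# Negative-binomial modelling of bout-level feeding-event counts with
# all-subsets QAIC model averaging (shrinkage) and concordance validation.

BOUT_TERMS <- c("log_n_dives", "log_n_dives_sq", "max_depth", "n_wiggles",
                "ascent_rate", "descent_rate", "n_steps", "surface_duration")

#' Standardized bout design matrix
#'
#' Builds the covariate set of the bout-scale prey-capture model from raw
#' bout covariates: log number of dives and its square, maximal depth,
#' wiggles, ascent and descent rates, steps, surface duration — each
#' centred and scaled to unit s.d. Centering/scaling parameters can be
#' frozen (from fit rows) and reapplied (to validation rows).
#'
#' The quadratic term is the square of the *standardized* log dive count
#' (not of the raw one): squaring after centring keeps the linear and
#' quadratic columns close to orthogonal, so their coefficients remain
#' separately identifiable.
#'
#' @param raw data.frame with columns `n_dives`, `max_depth`, `n_wiggles`,
#'   `ascent_rate`, `descent_rate`, `n_steps`, `surface_duration`.
#' @param center,scale optional frozen standardization parameters.
#' @param log_center,log_scale frozen centring/scaling of `log(n_dives)`
#'   used to build the quadratic term.
#' @return list: `z` (standardized matrix), `center`, `scale`,
#'   `log_center`, `log_scale`.
#' @export
bout_design <- function(raw, center = NULL, scale = NULL,
                        log_center = NULL, log_scale = NULL) {
  need <- c("n_dives", "max_depth", "n_wiggles", "ascent_rate",
            "descent_rate", "n_steps", "surface_duration")
  stop_if_not(all(need %in% names(raw)), "missing bout covariates: %s",
              paste(setdiff(need, names(raw)), collapse = ", "))
  stop_if_not(all(raw$n_dives >= 1), "n_dives must be >= 1")
  l <- log(raw$n_dives)
  if (is.null(log_center)) log_center <- mean(l)
  if (is.null(log_scale)) {
    log_scale <- stats::sd(l)
    if (!is.finite(log_scale) || log_scale == 0) log_scale <- 1
  }
  lz <- (l - log_center) / log_scale
  x <- cbind(log_n_dives = l,
             log_n_dives_sq = lz^2,
             max_depth = raw$max_depth,
             n_wiggles = raw$n_wiggles,
             ascent_rate = raw$ascent_rate,
             descent_rate = raw$descent_rate,
             n_steps = raw$n_steps,
             surface_duration = raw$surface_duration)
  s <- standardize_cols(x, center, scale)
  list(z = s$z, center = s$center, scale = s$scale,
       log_center = log_center, log_scale = log_scale)
}

#' Fit a negative-binomial regression for one covariate subset
#'
#' Maximum-likelihood NB regression (log link) of feeding-event counts on a
#' subset of the standardized bout covariates. Non-convergence is flagged
#' rather than thrown, so all-subsets enumeration can skip pathological
#' fits.
#'
#' @param table a `bout_table` with response `n_events`.
#' @param subset character vector of covariate names (see `bout_design`);
#'   `character(0)` fits the intercept-only model.
#' @param design optional precomputed [bout_design()] (frozen
#'   standardization).
#' @return list of class `nb_fit`: `coefficients`, `se`, `theta`, `logLik`,
#'   `k` (coefficients + 1 for the variance-inflation parameter), `fitted`,
#'   `converged`, `subset`, `model`.
#' @export
fit_nb <- function(table, subset = BOUT_TERMS, design = NULL) {
  stop_if_not("n_events" %in% names(table), "table needs response n_events")
  y <- table$n_events
  stop_if_not(all(y >= 0) && all(y == round(y)), "counts must be non-negative integers")
  if (is.null(design)) design <- bout_design(table)
  stop_if_not(all(subset %in% colnames(design$z)), "unknown covariates in subset")
  stop_if_not(length(y) > length(subset) + 2, "too few rows for this subset")
  dat <- data.frame(y = y)
  if (length(subset)) dat <- cbind(dat, as.data.frame(design$z[, subset, drop = FALSE]))
  fml <- if (length(subset)) {
    stats::as.formula(paste("y ~", paste(subset, collapse = " + ")))
  } else y ~ 1
  converged <- TRUE
  fit <- withCallingHandlers(
    tryCatch(MASS::glm.nb(fml, data = dat,
                          control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
             error = function(e) e),
    warning = function(w) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    })
  if (inherits(fit, "error")) {
    # theta diverging (equi- or under-dispersed data) breaks glm.nb; the
    # NB family's theta -> Inf boundary is the Poisson model, so fall back
    pfit <- tryCatch(stats::glm(fml, family = stats::poisson(), data = dat),
                     error = function(e) e)
    if (inherits(pfit, "error")) {
      return(structure(list(coefficients = NULL, se = NULL, theta = NA,
                            logLik = NA, k = length(subset) + 2, fitted = NULL,
                            converged = FALSE, subset = subset, model = NULL,
                            error = conditionMessage(fit)),
                       class = "nb_fit"))
    }
    sm <- summary(pfit)
    return(structure(list(coefficients = stats::coef(pfit),
                          se = sm$coefficients[, "Std. Error"],
                          theta = Inf,
                          logLik = as.numeric(stats::logLik(pfit)),
                          k = length(stats::coef(pfit)) + 1,
                          fitted = stats::fitted(pfit),
                          converged = all(is.finite(stats::coef(pfit))),
                          subset = subset, model = pfit),
                     class = "nb_fit"))
  }
  # theta hitting its iteration cap (e.g. equidispersed data) still yields a
  # usable mean model; only a broken fit is non-converged
  if (!converged && all(is.finite(stats::coef(fit)))) converged <- TRUE
  sm <- summary(fit)
  structure(list(coefficients = stats::coef(fit),
                 se = sm$coefficients[, "Std. Error"],
                 theta = fit$theta,
                 logLik = as.numeric(stats::logLik(fit)),
                 k = length(stats::coef(fit)) + 1,
                 fitted = stats::fitted(fit),
                 converged = converged && all(is.finite(stats::coef(fit))),
                 subset = subset,
                 model = fit),
            class = "nb_fit")
}

#' Overdispersion tests for bout counts
#'
#' Two complementary checks against the Poisson assumption:
#' (a) the auxiliary-regression test of `Var = mu + alpha * mu^2` — OLS of
#' `((y - mu)^2 - y) / mu` on `mu` (no intercept) under the Poisson fit,
#' one-sided for `alpha > 0`; (b) the NB-versus-Poisson likelihood-ratio
#' test with the boundary-corrected null, `p = 0.5 P(chi2_1 > LR)` (the
#' dispersion parameter sits on the boundary of its space under the null).
#'
#' @param table a `bout_table`.
#' @param subset covariates of the mean model (default all).
#' @return list: `dispersion` (alpha, statistic, p_value),
#'   `lrt` (statistic, p_value), `logLik_poisson`, `logLik_nb`.
#' @export
overdispersion_tests <- function(table, subset = BOUT_TERMS) {
  design <- bout_design(table)
  y <- table$n_events
  dat <- data.frame(y = y, as.data.frame(design$z[, subset, drop = FALSE]))
  fml <- stats::as.formula(paste("y ~", paste(subset, collapse = " + ")))
  pois <- stats::glm(fml, family = stats::poisson(), data = dat)
  mu <- stats::fitted(pois)
  zz <- ((y - mu)^2 - y) / mu
  aux <- stats::lm(zz ~ 0 + mu)
  alpha <- unname(stats::coef(aux)[1])
  tstat <- unname(summary(aux)$coefficients[1, "t value"])
  p_disp <- stats::pt(tstat, df = aux$df.residual, lower.tail = FALSE)
  nb <- fit_nb(table, subset, design)
  lr <- 2 * (nb$logLik - as.numeric(stats::logLik(pois)))
  lr <- max(0, lr)
  p_lrt <- 0.5 * stats::pchisq(lr, df = 1, lower.tail = FALSE)
  list(dispersion = list(alpha = alpha, statistic = tstat, p_value = p_disp),
       lrt = list(statistic = lr, p_value = p_lrt),
       logLik_poisson = as.numeric(stats::logLik(pois)),
       logLik_nb = nb$logLik)
}

#' Quasi-likelihood AIC
#'
#' `QAIC = -2 logL / c_hat + 2 k`, with `k` including the
#' variance-inflation parameter. With `c_hat = 1` this is the ordinary AIC.
#'
#' @param fit an `nb_fit` (or any list with `logLik` and `k`).
#' @param c_hat variance inflation factor; values below 1 are clamped to 1
#'   with a warning.
#' @return numeric QAIC.
#' @export
qaic <- function(fit, c_hat = 1) {
  if (c_hat < 1) {
    warning("c_hat < 1 clamped to 1")
    c_hat <- 1
  }
  -2 * fit$logLik / c_hat + 2 * fit$k
}

#' All-subsets QAIC model averaging with shrinkage
#'
#' Fits every subset of the bout covariates (the squared log-dive term only
#' ever entering together with the linear term), ranks models by QAIC with
#' `c_hat` estimated as the Pearson chi-square/df of the global model,
#' computes Akaike weights `w = exp(-Delta/2)` (normalized), keeps the
#' smallest set of top models whose cumulative weight reaches
#' `conf_level`, and averages coefficients over that set with shrinkage
#' (a coefficient counts as 0 in models that exclude it). Adjusted
#' (unconditional) standard errors follow the Burnham-Anderson formula
#' `sqrt(sum_m w_m (se_jm^2 + (b_jm - bbar_j)^2))`. Per-variable importance
#' is the summed weight of the retained models containing the term.
#'
#' @param table a `bout_table` with `n_events`.
#' @param c_hat override the estimated variance inflation.
#' @param conf_level cumulative-weight cutoff for the confidence set.
#' @param design optional frozen [bout_design()].
#' @return list of class `model_set`: `models` (per-model data.frame),
#'   `average` (term, estimate, adj_se, importance), `c_hat`, `design`,
#'   `n_models`, `n_failed`.
#' @export
enumerate_and_average <- function(table, c_hat = NULL, conf_level = 0.95,
                                  design = NULL) {
  if (is.null(design)) design <- bout_design(table)
  terms <- BOUT_TERMS
  stop_if_not(length(terms) <= 12, "too many covariates for enumeration")
  full <- fit_nb(table, terms, design)
  stop_if_not(full$converged, "global model did not converge")
  if (is.null(c_hat)) {
    y <- table$n_events
    mu <- full$fitted
    vfun <- mu + mu^2 / full$theta
    c_hat <- sum((y - mu)^2 / vfun) / (length(y) - full$k)
    if (c_hat < 1) c_hat <- 1
  }
  # enumerate subsets honouring marginality (square only with linear term)
  subsets <- list()
  other <- setdiff(terms, c("log_n_dives", "log_n_dives_sq"))
  for (mask in 0:(2^length(other) - 1)) {
    base <- other[bitwAnd(mask, 2^(seq_along(other) - 1)) > 0]
    subsets[[length(subsets) + 1]] <- base
    subsets[[length(subsets) + 1]] <- c("log_n_dives", base)
    subsets[[length(subsets) + 1]] <- c("log_n_dives", "log_n_dives_sq", base)
  }
  fits <- lapply(subsets, function(s) fit_nb(table, s, design))
  ok <- vapply(fits, `[[`, TRUE, "converged")
  n_failed <- sum(!ok)
  if (n_failed > 0) {
    warning(sprintf("%d model(s) failed to converge and were excluded", n_failed))
  }
  stop_if_not(any(ok), "no candidate model converged")
  fits <- fits[ok]
  subsets <- subsets[ok]
  q <- vapply(fits, qaic, 0, c_hat = c_hat)
  delta <- q - min(q)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  ord <- order(q)
  cumw <- cumsum(w[ord])
  n_keep <- which(cumw >= conf_level)[1]
  keep <- ord[seq_len(n_keep)]
  wk <- w[keep] / sum(w[keep])
  all_terms <- c("(Intercept)", terms)
  est <- matrix(0, length(keep), length(all_terms),
                dimnames = list(NULL, all_terms))
  sem <- matrix(0, length(keep), length(all_terms),
                dimnames = list(NULL, all_terms))
  pres <- matrix(FALSE, length(keep), length(all_terms),
                 dimnames = list(NULL, all_terms))
  for (i in seq_along(keep)) {
    f <- fits[[keep[i]]]
    est[i, names(f$coefficients)] <- f$coefficients
    sem[i, names(f$se)] <- f$se
    pres[i, names(f$coefficients)] <- TRUE
  }
  bbar <- colSums(wk * est)
  adj_se <- sqrt(colSums(wk * (sem^2 + sweep(est, 2, bbar)^2)))
  importance <- colSums(wk * pres)
  models <- data.frame(
    subset = vapply(subsets, function(s) {
      if (length(s)) paste(s, collapse = "+") else "(intercept)"
    }, ""),
    k = vapply(fits, `[[`, 0, "k"),
    logLik = vapply(fits, `[[`, 0, "logLik"),
    qaic = q, delta = delta, weight = w,
    in_conf_set = seq_along(fits) %in% keep)
  models <- models[order(models$qaic), ]
  rownames(models) <- NULL
  structure(list(models = models,
                 average = data.frame(term = all_terms, estimate = bbar,
                                      adj_se = adj_se,
                                      importance = importance,
                                      row.names = NULL),
                 c_hat = c_hat, design = design,
                 n_models = length(fits), n_failed = n_failed),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("QAIC model set: %d models (c_hat = %.3f), %d in 95%% confidence set\n",
              x$n_models, x$c_hat, sum(x$models$in_conf_set)))
  avg <- x$average
  avg$estimate <- round(avg$estimate, 3)
  avg$adj_se <- round(avg$adj_se, 3)
  avg$importance <- round(avg$importance, 2)
  print(avg, row.names = FALSE)
  invisible(x)
}

#' Predict mean counts from an averaged model
#'
#' @param object a `model_set`.
#' @param newdata data.frame of raw bout covariates; its columns are
#'   standardized with the parameters frozen in the model set.
#' @param ... unused.
#' @return predicted mean counts.
#' @export
predict.model_set <- function(object, newdata, ...) {
  des <- bout_design(newdata, center = object$design$center,
                     scale = object$design$scale,
                     log_center = object$design$log_center,
                     log_scale = object$design$log_scale)
  beta <- object$average$estimate
  names(beta) <- object$average$term
  eta <- beta[["(Intercept)"]] +
    as.vector(des$z[, BOUT_TERMS, drop = FALSE] %*% beta[BOUT_TERMS])
  exp(eta)
}

#' Concordance index between observed counts and predicted means
#'
#' Over all pairs with distinct observed values, the fraction predicted in
#' the same order, ties in prediction counting one half.
#'
#' @param observed,predicted equal-length numeric vectors (n >= 2).
#' @return list of class `c_index`: `c_index`, `n_concordant`,
#'   `n_discordant`, `n_tied`, `n_comparable`.
#' @export
c_index <- function(observed, predicted) {
  stop_if_not(length(observed) == length(predicted), "length mismatch")
  stop_if_not(length(observed) >= 2, "need at least 2 observations")
  if (length(unique(observed)) == 1) {
    warning("all observed values tied: concordance undefined")
    return(structure(list(c_index = NA_real_, n_concordant = 0,
                          n_discordant = 0, n_tied = 0, n_comparable = 0),
                     class = "c_index"))
  }
  do_ <- outer(observed, observed, "-")
  dp <- outer(predicted, predicted, "-")
  comp <- upper.tri(do_) & do_ != 0
  s <- sign(do_[comp]) * sign(dp[comp])
  conc <- sum(s > 0)
  disc <- sum(s < 0)
  tied <- sum(s == 0)
  structure(list(c_index = (conc + 0.5 * tied) / (conc + disc + tied),
                 n_concordant = conc, n_discordant = disc, n_tied = tied,
                 n_comparable = conc + disc + tied),
            class = "c_index")
}

#' Cross-validated concordance of the averaged prey-capture model
#'
#' Runs the full enumeration-and-averaging pipeline on the fit rows
#' (standardization parameters frozen from those rows), predicts the
#' validation rows, and reports in-sample and validation concordance. The
#' motivating analysis used a single 36/38 bout split.
#'
#' @param table a `bout_table`.
#' @param fit_rows,val_rows disjoint integer row sets; if omitted, a random
#'   `n_fit` / rest split is drawn with `seed`.
#' @param n_fit fit-set size for the random split (default 36).
#' @param seed split seed.
#' @param ... passed to [enumerate_and_average()].
#' @return list of class `cv_result`: `model_set`, `c_fit`, `c_val`,
#'   `fit_rows`, `val_rows`.
#' @export
cross_validate <- function(table, fit_rows = NULL, val_rows = NULL,
                           n_fit = 36, seed = 1, ...) {
  n <- nrow(table)
  if (is.null(fit_rows)) {
    set.seed(seed)
    fit_rows <- sort(sample.int(n, n_fit))
  }
  if (is.null(val_rows)) val_rows <- setdiff(seq_len(n), fit_rows)
  stop_if_not(length(intersect(fit_rows, val_rows)) == 0,
              "fit and validation rows overlap (leakage)")
  fit_tab <- table[fit_rows, , drop = FALSE]
  val_tab <- table[val_rows, , drop = FALSE]
  ms <- enumerate_and_average(fit_tab, ...)
  c_fit <- c_index(fit_tab$n_events, predict(ms, fit_tab))
  c_val <- c_index(val_tab$n_events, predict(ms, val_tab))
  structure(list(model_set = ms, c_fit = c_fit, c_val = c_val,
                 fit_rows = fit_rows, val_rows = val_rows),
            class = "cv_result")
}
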