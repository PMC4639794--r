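#' Generate gridded monthly SST fields with a planted dipole mode and a
#' front-responsive isotherm
#'
#' Builds summer (January-March) monthly SST on a rectilinear grid covering
#' both the combined South Atlantic-Indian dipole (SAIOD) domain
#' (10-50 degS, 50 degW-150 degE) and the polar-front sector south of the
#' subantarctic colony. Two structures are planted:
#'
#' * a unit-norm dipole anomaly pattern (warm poles in the southwest of the
#'   Atlantic and Indian basins, cold poles to the northeast) multiplied by a
#'   yearly standard-normal amplitude, plus isotropic noise scaled so the
#'   planted mode accounts for `planted_var_frac` of the February-March
#'   anomaly variance over the SAIOD domain (under sqrt-cos-latitude
#'   weighting, the convention [eof_leading()] uses);
#' * in the front sector (47-56 degS, 48-56 degE) a linear-in-latitude base
#'   field plus a spatially uniform yearly anomaly, so that the latitude of
#'   the 5 degC surface isotherm responds to the sector-box SST anomaly at
#'   exactly `pf_slope` km per degC (southward positive).
#'
#' The front sector carries its own (smaller) noise level: subantarctic SST
#' variance is much lower than the subtropical dipole variance the EOF noise
#' is calibrated against.
#'
#' @param n_years number of years (default 33, a 1979-2011-style record).
#' @param lat_step,lon_step grid resolution in degrees.
#' @param planted_var_frac fraction of SAIOD-domain variance explained by the
#'   dipole mode, in (0, 1]; default 0.27.
#' @param pattern_scale dipole amplitude scale (degC; the pattern itself has
#'   unit norm, so this sets the physical size of the anomalies).
#' @param pf_slope planted front displacement per degC of box anomaly
#'   (km per degC, southward positive); default 130.
#' @param box_sd s.d. of the yearly uniform front-sector anomaly (degC).
#' @param noise_sd per-cell noise s.d. (degC) outside the front sector;
#'   `NULL` (default) computes it from `planted_var_frac`. Passing 0 with
#'   `planted_var_frac < 1` is rejected as incompatible.
#' @param noise_sd_pf per-cell noise s.d. inside the front sector.
#' @param pf_coupling set `FALSE` to switch the front-sector variability off
#'   (no box anomaly, no sector noise), leaving a pure dipole-plus-noise
#'   anomaly field (exactly rank-one when `planted_var_frac = 1`).
#' @param seed integer seed.
#' @return list of class `sst_field_sim`: `field` (an `sst_field`: `lat`,
#'   `lon`, `time` data.frame (year, month), `sst` array lat x lon x time)
#'   and `truth` (pattern, pc_series, box_anomaly, iso_lat, pf_slope,
#'   planted_var_frac, noise_sd).
#' @export
gen_sst_fields <- function(n_years = 33, lat_step = 2, lon_step = 2,
                           planted_var_frac = 0.27, pattern_scale = 15,
                           pf_slope = 130, box_sd = 0.5,
                           noise_sd = NULL, noise_sd_pf = 0.1,
                           pf_coupling = TRUE, seed = 1) {
  stop_if_not(planted_var_frac > 0 && planted_var_frac <= 1,
              "planted_var_frac must be in (0, 1]")
  lat <- seq(-56, -10, by = lat_step)
  lon <- seq(-50, 150, by = lon_step)
  months <- 1:3
  nt <- n_years * length(months)
  time <- data.frame(year = rep(seq_len(n_years), each = length(months)),
                     month = rep(months, n_years))

  in_pf <- outer(lat >= -56 & lat <= -47, lon >= 48 & lon <= 56, "&")
  in_saiod <- outer(lat >= -50 & lat <= -10, lon >= -50 & lon <= 150, "&")

  # dipole pattern: tilted warm SW / cold NE poles in each basin, supported
  # on the SAIOD domain outside the front sector, unit norm
  gauss2 <- function(latc, lonc, slat, slon) {
    outer(exp(-(lat - latc)^2 / (2 * slat^2)),
          exp(-(lon - lonc)^2 / (2 * slon^2)))
  }
  pattern <- gauss2(-40, -35, 8, 14) - gauss2(-20, 0, 8, 14) +
    gauss2(-42, 65, 8, 16) - gauss2(-22, 115, 8, 16)
  pattern[!in_saiod | in_pf] <- 0
  pattern <- pattern / sqrt(sum(pattern^2))

  # noise calibration: the EOF stage sees February-March mean anomalies
  # weighted by sqrt(cos(lat)); solve for the noise level that leaves the
  # dipole holding planted_var_frac of that variance
  w2 <- outer(cos(lat * pi / 180), rep(1, length(lon)))
  w2_dom <- w2 * (in_saiod & !in_pf)
  dip_var <- pattern_scale^2 * sum(w2_dom * pattern^2)
  n_mon_eof <- 2 # Feb-Mar mean halves the noise variance
  if (is.null(noise_sd)) {
    if (planted_var_frac == 1) {
      noise_sd <- 0
    } else {
      tot_w2 <- sum(w2 * in_saiod)
      noise_sd <- sqrt(n_mon_eof * dip_var *
                         (1 - planted_var_frac) / (planted_var_frac * tot_w2))
    }
  } else if (noise_sd == 0 && planted_var_frac < 1) {
    stop("planted_var_frac < 1 is incompatible with noise_sd = 0", call. = FALSE)
  }

  set.seed(seed)
  pc <- stats::rnorm(n_years)
  box_anom <- if (pf_coupling) stats::rnorm(n_years, 0, box_sd) else rep(0, n_years)
  if (!pf_coupling) noise_sd_pf <- 0
  grad <- KM_PER_DEG_LAT / pf_slope # degC per degree latitude
  lat0 <- -51
  base_pf <- 5 + grad * (lat - lat0)
  base_open <- pmin(27, 5 + 0.6 * (lat + 51))

  sst <- array(0, dim = c(length(lat), length(lon), nt))
  for (k in seq_len(nt)) {
    yr <- time$year[k]; mo <- time$month[k]
    f <- outer(base_open, rep(1, length(lon))) +
      1.5 * cos(2 * pi * (mo - 2) / 12)
    f <- f + pattern_scale * pc[yr] * pattern
    noise <- matrix(stats::rnorm(length(lat) * length(lon), 0, noise_sd),
                    length(lat), length(lon))
    f <- f + noise * !in_pf
    # front sector: linear base + uniform yearly anomaly + its own noise
    fpf <- outer(base_pf, rep(1, length(lon))) + box_anom[yr] +
      matrix(stats::rnorm(length(lat) * length(lon), 0, noise_sd_pf),
             length(lat), length(lon))
    f[in_pf] <- fpf[in_pf]
    sst[, , k] <- f
  }
  field <- structure(list(lat = lat, lon = lon, time = time, sst = sst,
                          units = "degC"), class = "sst_field")
  iso_lat <- lat0 - box_anom / grad
  structure(list(field = field,
                 truth = list(pattern = pattern, pc_series = pc,
                              box_anomaly = box_anom, iso_lat = iso_lat,
                              pf_slope = pf_slope,
                              planted_var_frac = planted_var_frac,
                              noise_sd = noise_sd)),
            class = "sst_field_sim")
}

#' Serialize / read an SST field as long-format CSV
#'
#' Columns `lat`, `lon`, `year`, `month`, `sst` (degC); a plain-text stand-in
#' for a gridded file with dims (lat, lon, time) and variable `sst`.
#'
#' @param field an `sst_field`.
#' @param path file path.
#' @return `read_sst_csv` returns an `sst_field`.
#' @export
write_sst_csv <- function(field, path) {
  stop_if_not(inherits(field, "sst_field"), "not an sst_field")
  idx <- expand.grid(lat = field$lat, lon = field$lon,
                     t = seq_len(nrow(field$time)))
  df <- data.frame(lat = idx$lat, lon = idx$lon,
                   year = field$time$year[idx$t],
                   month = field$time$month[idx$t],
                   sst = as.vector(field$sst))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sst_csv
#' @export
read_sst_csv <- function(path) {
  df <- utils::read.csv(path)
  lat <- sort(unique(df$lat)); lon <- sort(unique(df$lon))
  tim <- unique(df[order(df$year, df$month), c("year", "month")])
  rownames(tim) <- NULL
  sst <- array(NA_real_, dim = c(length(lat), length(lon), nrow(tim)))
  ti <- match(paste(df$year, df$month), paste(tim$year, tim$month))
  sst[cbind(match(df$lat, lat), match(df$lon, lon), ti)] <- df$sst
  structure(list(lat = lat, lon = lon, time = tim, sst = sst, units = "degC"),
            class = "sst_field")
}
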