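#' Monthly-climatology SST anomalies
#'
#' Subtracts the per-cell, per-calendar-month mean over the baseline years
#' from a gridded SST field.
#'
#' @param field an `sst_field` (see [gen_sst_fields()]).
#' @param baseline_years years (values of `field$time$year`) defining the
#'   climatology; default all years.
#' @return an `sst_field` whose `sst` holds anomalies (degC).
#' @export
anomalies <- function(field, baseline_years = NULL) {
  stop_if_not(inherits(field, "sst_field"), "not an sst_field")
  yrs <- baseline_years %||% unique(field$time$year)
  stop_if_not(all(yrs %in% field$time$year), "baseline years outside record")
  out <- field
  for (mo in unique(field$time$month)) {
    base_idx <- which(field$time$month == mo & field$time$year %in% yrs)
    stop_if_not(length(base_idx) > 0,
                "calendar month %d missing from baseline", mo)
    clim <- apply(field$sst[, , base_idx, drop = FALSE], c(1, 2), mean)
    all_idx <- which(field$time$month == mo)
    for (k in all_idx) out$sst[, , k] <- field$sst[, , k] - clim
  }
  out
}

# Subset helper: indices of lat/lon within closed ranges.
range_idx <- function(v, r) which(v >= min(r) & v <= max(r))

#' Box-mean SST anomaly series
#'
#' Area-weighted (cos latitude) mean anomaly over a lat/lon box and a set of
#' calendar months, one value per year. Defaults are the foraging box south
#' of the colony, 47-53 degS / 49-55 degE, during February-March.
#'
#' @param anoms an anomaly `sst_field` (from [anomalies()]).
#' @param lat_range,lon_range box edges in degrees (south negative).
#' @param months calendar months included.
#' @return data.frame `year`, `ssta` (degC).
#' @export
box_ssta <- function(anoms, lat_range = c(-53, -47), lon_range = c(49, 55),
                     months = c(2, 3)) {
  stop_if_not(inherits(anoms, "sst_field"), "not an sst_field")
  li <- range_idx(anoms$lat, lat_range)
  gi <- range_idx(anoms$lon, lon_range)
  stop_if_not(length(li) > 0 && length(gi) > 0, "box does not intersect grid")
  w <- cos(anoms$lat[li] * pi / 180)
  wmat <- outer(w, rep(1, length(gi)))
  yrs <- sort(unique(anoms$time$year))
  ssta <- vapply(yrs, function(y) {
    ks <- which(anoms$time$year == y & anoms$time$month %in% months)
    stop_if_not(length(ks) > 0, "no requested months in year %d", y)
    vals <- apply(anoms$sst[li, gi, ks, drop = FALSE], c(1, 2), mean)
    sum(wmat * vals) / sum(wmat)
  }, 0)
  data.frame(year = yrs, ssta = ssta)
}

#' Locate the polar front from a surface isotherm
#'
#' For each year, the months in `months` are averaged, and in every
#' longitude column of the sector the northernmost latitude where SST
#' crosses the isotherm is found by linear interpolation between adjacent
#' grid latitudes. The sector-mean latitude is reported together with its
#' anomaly (degrees, positive = south of the period mean), the southward
#' displacement in km, and the great-circle distance to the colony.
#'
#' @param field an `sst_field` of raw SST (degC).
#' @param isotherm isotherm defining the front (degC); default 5, the summer
#'   surface signature of the polar front's northern limit.
#' @param sector longitude range (deg E) over which front latitude is
#'   averaged; default 50-54 degE.
#' @param months calendar months averaged ("summer"); default Jan-Mar.
#' @param colony named numeric `c(lat=, lon=)`; default Possession Island.
#' @return data.frame of class `pf_series`: `year`, `lat`, `anomaly_deg`
#'   (positive south), `displacement_km` (positive south), `dist_colony_km`.
#' @export
locate_pf <- function(field, isotherm = 5, sector = c(50, 54),
                      months = 1:3, colony = c(lat = -46.43, lon = 51.86)) {
  stop_if_not(inherits(field, "sst_field"), "not an sst_field")
  gi <- range_idx(field$lon, sector)
  stop_if_not(length(gi) > 0, "sector does not intersect grid")
  lat <- field$lat
  ord <- order(lat, decreasing = TRUE) # scan from north
  yrs <- sort(unique(field$time$year))
  lat_pf <- vapply(yrs, function(y) {
    ks <- which(field$time$year == y & field$time$month %in% months)
    stop_if_not(length(ks) > 0, "no requested months in year %d", y)
    fmean <- apply(field$sst[, gi, ks, drop = FALSE], c(1, 2), mean)
    crossings <- vapply(seq_along(gi), function(j) {
      s <- fmean[ord, j] - isotherm
      for (i in seq_len(length(s) - 1)) {
        if (s[i] == 0) return(lat[ord][i])
        if (s[i] * s[i + 1] <= 0) {
          l1 <- lat[ord][i]; l2 <- lat[ord][i + 1]
          return(l1 + (l2 - l1) * s[i] / (s[i] - s[i + 1]))
        }
      }
      NA_real_
    }, 0)
    if (all(is.na(crossings))) return(NA_real_)
    if (anyNA(crossings)) {
      warning(sprintf("isotherm not crossed in %d column(s), year %d",
                      sum(is.na(crossings)), y))
    }
    mean(crossings, na.rm = TRUE)
  }, 0)
  stop_if_not(!all(is.na(lat_pf)), "isotherm never crossed in sector")
  mean_lat <- mean(lat_pf, na.rm = TRUE)
  dist_km <- vapply(lat_pf, function(phi) {
    if (is.na(phi)) return(NA_real_)
    geosphere::distHaversine(c(mean(sector), phi),
                             c(colony[["lon"]], colony[["lat"]])) / 1000
  }, 0)
  out <- data.frame(year = yrs, lat = lat_pf,
                    anomaly_deg = mean_lat - lat_pf,
                    displacement_km = (mean_lat - lat_pf) * KM_PER_DEG_LAT,
                    dist_colony_km = dist_km)
  class(out) <- c("pf_series", "data.frame")
  out
}

#' Leading EOF of SST anomalies (dipole index)
#'
#' Principal-component analysis of yearly month-averaged anomalies over a
#' lat/lon domain: cells are weighted by sqrt(cos latitude), the year-by-cell
#' matrix is column-centred and decomposed by SVD (covariance-based PCA).
#' The leading principal component is standardized to unit variance; its
#' sign is set so that a positive index corresponds to positive loadings in
#' the southwest of the two basins. Defaults construct the subtropical
#' Atlantic-Indian dipole index: February-March anomalies over 10-50 degS,
#' 50 degW-150 degE.
#'
#' @param anoms an anomaly `sst_field`.
#' @param lat_range,lon_range analysis domain.
#' @param months calendar months averaged per year.
#' @return list of class `saiod_index`: `index` (data.frame `year`, `pc`),
#'   `explained_var` (fraction in (0, 1]), `pattern` (loadings, lat x lon,
#'   NA outside the domain), `eigenvalues`, and `decomp` (weighted centred
#'   matrix and its SVD, for reconstruction checks).
#' @export
eof_leading <- function(anoms, lat_range = c(-50, -10),
                        lon_range = c(-50, 150), months = c(2, 3)) {
  stop_if_not(inherits(anoms, "sst_field"), "not an sst_field")
  yrs <- sort(unique(anoms$time$year))
  stop_if_not(length(yrs) >= 3, "need at least 3 years for an EOF")
  li <- range_idx(anoms$lat, lat_range)
  gi <- range_idx(anoms$lon, lon_range)
  stop_if_not(length(li) > 0 && length(gi) > 0, "domain does not intersect grid")
  w <- sqrt(cos(anoms$lat[li] * pi / 180))
  wmat <- outer(w, rep(1, length(gi)))
  Y <- t(vapply(yrs, function(y) {
    ks <- which(anoms$time$year == y & anoms$time$month %in% months)
    stop_if_not(length(ks) > 0, "no requested months in year %d", y)
    as.vector(apply(anoms$sst[li, gi, ks, drop = FALSE], c(1, 2), mean) * wmat)
  }, numeric(length(li) * length(gi))))
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  sv <- svd(Yc)
  ev <- sv$d^2
  pc_raw <- sv$u[, 1] * sv$d[1]
  loading <- matrix(sv$v[, 1] / wmat, length(li), length(gi))
  # sign convention: positive index <=> warm SW quadrants of the two basins
  sw <- outer(anoms$lat[li] >= -50 & anoms$lat[li] <= -30,
              (anoms$lon[gi] >= -50 & anoms$lon[gi] <= 0) |
                (anoms$lon[gi] >= 50 & anoms$lon[gi] <= 100), "&")
  if (mean(loading[sw]) < 0) {
    pc_raw <- -pc_raw
    loading <- -loading
  }
  pattern <- matrix(NA_real_, length(anoms$lat), length(anoms$lon))
  pattern[li, gi] <- loading
  structure(list(index = data.frame(year = yrs,
                                    pc = as.numeric(scale(pc_raw))),
                 explained_var = ev[1] / sum(ev),
                 pattern = pattern,
                 eigenvalues = ev,
                 decomp = list(Y = Yc, svd = sv)),
            class = "saiod_index")
}

#' Regression of polar-front displacement on box SST anomaly
#'
#' Ordinary least squares of southward front displacement (km) on the yearly
#' box-mean SST anomaly (degC), the coupling reported as "km southward per
#' degree of warming".
#'
#' @param pf a `pf_series` from [locate_pf()].
#' @param ssta data.frame `year`, `ssta` from [box_ssta()].
#' @return list of class `pf_slope_fit`: `slope` (km per degC), `intercept`,
#'   `r_squared`, `F`, `df`, `p_value`, `n`, and the underlying `lm` fit.
#' @export
pf_ssta_slope <- function(pf, ssta) {
  d <- merge(as.data.frame(pf)[, c("year", "displacement_km")], ssta,
             by = "year")
  d <- d[stats::complete.cases(d), ]
  stop_if_not(nrow(d) >= 5, "need at least 5 paired years")
  stop_if_not(stats::sd(d$ssta) > 0, "SSTA has zero variance")
  fit <- stats::lm(displacement_km ~ ssta, data = d)
  s <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 F = unname(s$fstatistic[1]),
                 df = unname(s$fstatistic[2:3]),
                 p_value = stats::pf(s$fstatistic[1], s$fstatistic[2],
                                     s$fstatistic[3], lower.tail = FALSE),
                 n = nrow(d), fit = fit),
            class = "pf_slope_fit")
}
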