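.DEFAULT_TMEAN_NORMALS <- c(-32, -30, -22, -13, -1, 7, 13, 10, 3, -9, -25, -30)
.DEFAULT_PREC_NORMALS <- c(15, 12, 12, 14, 20, 35, 45, 40, 30, 25, 18, 15)

.ar1_anomaly <- function(n, sd, ar1) {
  a <- numeric(n)
  if (sd == 0 || n == 0) return(a)
  innov_sd <- sd * sqrt(1 - ar1^2)
  a[1] <- stats::rnorm(1, 0, sd)
  if (n > 1) for (i in 2:n) a[i] <- ar1 * a[i - 1] + stats::rnorm(1, 0, innov_sd)
  a
}

.synth_monthly <- function(years, tmean_normals, prec_normals, interannual_sd,
                           ar1, monthly_sd, prec_rel_sd, trend = NULL) {
  n <- length(years)
  anom <- .ar1_anomaly(n, interannual_sd, ar1)
  if (!is.null(trend)) anom <- anom + trend
  tm <- matrix(rep(tmean_normals, each = n), n, 12L) + anom +
    if (monthly_sd > 0) matrix(stats::rnorm(n * 12L, 0, monthly_sd), n, 12L) else 0
  pr <- matrix(rep(prec_normals, each = n), n, 12L)
  if (prec_rel_sd > 0) {
    # lognormal multiplicative noise with unit mean
    pr <- pr * matrix(exp(stats::rnorm(n * 12L, -prec_rel_sd^2 / 2, prec_rel_sd)),
                      n, 12L)
  }
  list(tmean = tm, prec = pr)
}

#' Generate a recent ("CRU-like") monthly climate series
#'
#' Monthly values are climatological normals plus a yearly AR(1) temperature
#' anomaly (stationary standard deviation `interannual_sd`, autocorrelation
#' `ar1`) plus monthly white noise; precipitation gets unit-mean lognormal
#' multiplicative noise. Deterministic per seed.
#'
#' @param years integer years, default 1934:2013
#' @param tmean_normals,prec_normals numeric(12) monthly normals (degC, mm);
#'   defaults emulate a continental subarctic station
#' @param interannual_sd stationary SD of the yearly anomaly, degC
#' @param ar1 anomaly autocorrelation, in \[0, 1)
#' @param monthly_sd SD of monthly white noise, degC
#' @param prec_rel_sd relative (log-scale) SD of precipitation noise
#' @param seed integer seed
#' @param label series label
#' @return a [ClimateSeries-class]
#' @export
genRecentClimate <- function(years = 1934:2013,
                             tmean_normals = .DEFAULT_TMEAN_NORMALS,
                             prec_normals = .DEFAULT_PREC_NORMALS,
                             interannual_sd = 0.6, ar1 = 0.3, monthly_sd = 0.8,
                             prec_rel_sd = 0.3, seed = 1L, label = "recent") {
  if (!length(years)) stop("year span is empty")
  stopifnot(interannual_sd >= 0, abs(ar1) < 1)
  set.seed(seed)
  m <- .synth_monthly(years, tmean_normals, prec_normals, interannual_sd, ar1,
                      monthly_sd, prec_rel_sd)
  ClimateSeries(years, m$tmean, m$prec, label = label,
                metadata = list(generator = "genRecentClimate", seed = seed))
}

#' Long-term temperature trend of the paleo generator
#'
#' A smooth anomaly: `amplitude` degC at the series start declining along a
#' cosine ramp to zero at `min_before_end` years before the series end, then
#' recovering by `recover_amplitude` degC to the end (recent warming).
#'
#' @param years integer years of the series
#' @param amplitude early-to-minimum cooling, degC (default 2)
#' @param min_before_end years before the series end at which the minimum
#'   sits (default 200)
#' @param recover_amplitude warming from the minimum to the series end, degC
#' @return numeric anomaly per year, degC
#' @export
paleoTrend <- function(years, amplitude = 2, min_before_end = 200,
                       recover_amplitude = 0.5) {
  t_end <- years[length(years)]
  t_min <- t_end - min_before_end
  t0 <- years[1]
  a <- numeric(length(years))
  dec <- years <= t_min
  s <- (years[dec] - t0) / (t_min - t0)
  a[dec] <- amplitude * (1 + cos(pi * s)) / 2
  rec <- !dec
  if (any(rec)) {
    s2 <- (years[rec] - t_min) / (t_end - t_min)
    a[rec] <- recover_amplitude * (1 - cos(pi * s2)) / 2
  }
  a
}

#' Generate a millennial paleo climate series
#'
#' As [genRecentClimate()] plus the long-term trend of [paleoTrend()]: a
#' Holocene-style cooling of `trend_amplitude` degC from the series start to a
#' minimum `trend_min_before_end` years before the end, followed by a recent
#' recovery. With noise switched off, the first year's summer mean exceeds
#' the minimum-year summer mean by exactly `trend_amplitude`.
#'
#' @inheritParams genRecentClimate
#' @param years integer years, default -3982:2013
#' @param trend_amplitude cooling amplitude, degC (default 2)
#' @param trend_min_before_end minimum position, years before series end
#'   (default 200)
#' @param recover_amplitude recent warming, degC (default 1)
#' @return a [ClimateSeries-class]
#' @export
genPaleoSeries <- function(years = -3982:2013,
                           tmean_normals = .DEFAULT_TMEAN_NORMALS,
                           prec_normals = .DEFAULT_PREC_NORMALS,
                           interannual_sd = 0.6, ar1 = 0.3, monthly_sd = 0,
                           prec_rel_sd = 0.15, trend_amplitude = 2,
                           trend_min_before_end = 200, recover_amplitude = 0.5,
                           seed = 1L, label = "paleo") {
  if (length(years) < 1000) stop("paleo span must cover at least 1000 years")
  set.seed(seed)
  trend <- paleoTrend(years, trend_amplitude, trend_min_before_end,
                      recover_amplitude)
  m <- .synth_monthly(years, tmean_normals, prec_normals, interannual_sd, ar1,
                      monthly_sd, prec_rel_sd, trend = trend)
  ClimateSeries(years, m$tmean, m$prec, label = label,
                metadata = list(generator = "genPaleoSeries", seed = seed))
}
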