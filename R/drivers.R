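# Evaluate an expression with a fixed RNG seed, restoring the caller's RNG
# state afterwards. Keeps every generator deterministic and side-effect free.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Stationary AR(1) noise with given marginal sd and lag-1 correlation.
.ar1 <- function(n, sd, phi) {
  if (sd <= 0) return(numeric(n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  stats::filter(e, phi, method = "recursive", init = stats::rnorm(1, 0, sd))
}

#' Generate a half-hourly driver series
#'
#' Produces photosynthetically active radiation (PAR), air and soil
#' temperature and water level on an equidistant 30-min grid with sinusoidal
#' annual and diurnal cycles plus autocorrelated (AR(1)) noise. PAR is exactly
#' zero outside the day-length window (which never reaches midnight at the
#' emulated latitude), soil temperature is a damped, lagged copy of the air
#' temperature cycle, and the water level fluctuates around the scenario's
#' site mean.
#'
#' @param scenario a [site_scenario()]; supplies the mean air temperature,
#'   mean water level and the seed.
#' @param start,end `Date`; first and last day (inclusive) of the series.
#'   Defaults cover the scenario's hydrological year.
#' @param mean_t_air annual mean air temperature, degC (default taken from
#'   the scenario, itself defaulting to 9.9).
#' @return `data.frame` with columns `timestamp` (POSIXct UTC, 30-min),
#'   `par` (umol m-2 s-1), `t_air`, `t_soil` (degC), `wl` (m, negative below
#'   surface).
#' @examples
#' drv <- generate_drivers(open_site_scenario(),
#'                         as.Date("2020-11-01"), as.Date("2020-11-07"))
#' range(drv$par)
#' @export
generate_drivers <- function(scenario,
                             start = scenario$hydro_year_start,
                             end = scenario$hydro_year_start + 364,
                             mean_t_air = scenario$mean_t_air) {
  start <- as.Date(start); end <- as.Date(end)
  if (end < start) stop("empty date span")
  ts <- seq(as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
            as.POSIXct(paste(end, "23:30:00"), tz = "UTC"),
            by = 1800)
  n <- length(ts)
  lt <- as.POSIXlt(ts, tz = "UTC")
  doy <- lt$yday + 1 + (lt$hour + lt$min / 60) / 24
  hour <- lt$hour + lt$min / 60

  seasonal <- cos(2 * pi * (doy - 196) / 365.25)   # peak mid-July
  diurnal <- cos(2 * pi * (hour - 14) / 24)        # peak 14:00

  with_seed(scenario$seed, {
    t_air <- mean_t_air + 8.5 * seasonal + 3.5 * diurnal + .ar1(n, 2.0, 0.95)
    seasonal_lag <- cos(2 * pi * (doy - 196 - 15) / 365.25)
    diurnal_lag <- cos(2 * pi * (hour - 17) / 24)
    t_soil <- mean_t_air + 6.0 * seasonal_lag + 1.2 * diurnal_lag +
      .ar1(n, 0.8, 0.97)

    daylen <- 12 + 4.8 * sin(2 * pi * (doy - 80) / 365.25)
    sunrise <- 12 - daylen / 2
    frac <- (hour - sunrise) / daylen
    elev <- ifelse(frac > 0 & frac < 1, sin(pi * frac), 0)
    par_max <- 900 + 600 * seasonal
    cloud <- stats::plogis(.ar1(n, 1.5, 0.98) + 1.0)  # 0..1, autocorrelated
    par <- pmax(par_max, 0) * elev^1.2 * (0.25 + 0.75 * cloud)
    par[elev <= 0] <- 0

    wl <- scenario$mean_wl + 0.06 * cos(2 * pi * (doy - 105) / 365.25) +
      .ar1(n, 0.03, 0.99)
    wl <- pmin(wl, 0.05)
  })

  data.frame(timestamp = ts, par = as.numeric(par), t_air = as.numeric(t_air),
             t_soil = as.numeric(t_soil), wl = as.numeric(wl))
}
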