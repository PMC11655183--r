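#' True per-step source fluxes for one microform
#'
#' Evaluates the generator's "true" models on a driver series: Lloyd-Taylor
#' respiration (soil temperature for ground microforms, air temperature for
#' the branch source) and the rectangular-hyperbola light response. Values
#' are flux densities per m2 of source — ground area for microforms, leaf
#' area for the branch.
#'
#' @param mf a [microform_spec()].
#' @param drivers driver series from [generate_drivers()].
#' @return `data.frame` with `timestamp`, `gpp`, `reco`, `nee` in
#'   g CO2-C m-2 of source 30 min-1; `nee = gpp + reco` exactly.
#' @export
true_flux <- function(mf, drivers) {
  stopifnot(inherits(mf, "microform_spec"))
  if (any(drivers$par < 0)) stop("PAR must be >= 0")
  t_drv <- if (identical(mf$name, "branch")) drivers$t_air else drivers$t_soil
  reco <- lloyd_taylor(t_drv, mf$r_ref, mf$e0) / 2
  gpp <- light_response(drivers$par, mf$alpha, mf$gp_max) / 2
  data.frame(timestamp = drivers$timestamp, gpp = gpp, reco = reco,
             nee = gpp + reco)
}

#' Generate synthetic eddy-covariance records
#'
#' The true ecosystem flux is the areal-share-weighted sum of the ground
#' microform fluxes plus the LAI-weighted branch flux. Gaussian noise is
#' added separately to the GPP and Reco components (so the NEE identity and
#' the sign discipline survive), records receive quality flags and random
#' gaps, and a gap-free "gapfilled" twin — standing in for a standard
#' gap-filling step, which is out of scope — is carried in the same table.
#'
#' @param scenario a [site_scenario()].
#' @param drivers driver series from [generate_drivers()].
#' @param noise_sd standard deviation of the half-hourly NEE noise,
#'   g CO2-C m-2 30 min-1 (split between components). 0 gives exact truth.
#' @param gap_fraction fraction of records replaced by gaps, in `[0, 1)`.
#' @param seed integer seed.
#' @return `data.frame` with columns `timestamp`; `nee`, `gpp`, `reco`
#'   (complete, gap-filled series, g CO2-C m-2 30 min-1, `nee = gpp + reco`);
#'   `nee_obs` (measured NEE, `NA` at gaps); `qc_flag` (0/1/2, `NA` at gaps);
#'   `gapfilled` (`TRUE` where the complete series is filled, not measured).
#' @export
generate_ec <- function(scenario, drivers, noise_sd = 0.02,
                        gap_fraction = 0.1, seed = scenario$seed + 1L) {
  if (gap_fraction < 0 || gap_fraction >= 1)
    stop("gap_fraction must be in [0, 1)")
  shares <- ground_shares(scenario)
  if (abs(sum(shares) - 1) > 1e-9) stop("areal shares must sum to 1")
  n <- nrow(drivers)
  gpp_t <- numeric(n); reco_t <- numeric(n)
  for (mf in scenario$microforms) {
    tf <- true_flux(mf, drivers)
    w <- if (identical(mf$name, "branch"))
      lai_at(scenario, as.Date(drivers$timestamp, tz = "UTC"))
    else mf$areal_share
    gpp_t <- gpp_t + w * tf$gpp
    reco_t <- reco_t + w * tf$reco
  }
  with_seed(seed, {
    if (noise_sd > 0) {
      gpp <- pmin(gpp_t + stats::rnorm(n, 0, noise_sd / sqrt(2)), 0)
      reco <- pmax(reco_t + stats::rnorm(n, 0, noise_sd / sqrt(2)), 0)
    } else {
      gpp <- gpp_t; reco <- reco_t
    }
    gap <- stats::runif(n) < gap_fraction
    qc <- sample(0:2, n, replace = TRUE, prob = c(0.75, 0.17, 0.08))
  })
  nee <- gpp + reco
  data.frame(timestamp = drivers$timestamp,
             nee = nee, gpp = gpp, reco = reco,
             nee_obs = ifelse(gap, NA_real_, nee),
             qc_flag = ifelse(gap, NA_integer_, qc),
             gapfilled = gap)
}

# Slope (ppm s-1) that compute_flux() maps onto flux_per_s (g C m-2 s-1)
# for the given chamber geometry; exact algebraic inverse of compute_flux.
.flux_to_slope <- function(flux_per_s, volume, area, t_air_inside, pressure) {
  flux_per_s * (.R_GAS * (t_air_inside + .T0K) * area) /
    (1e-6 * pressure * volume * .M_C)
}

#' Generate a synthetic chamber measurement campaign
#'
#' For every campaign date, surface source and chamber type, closure traces
#' of 120-180 s at 1 Hz are generated whose underlying concentration slope is
#' the true source flux converted to ppm s-1 through the ideal-gas relation
#' (the exact inverse of [compute_flux()]), plus white analyzer noise.
#' Closures are spread from pre-dawn to mid-afternoon; at each closure slot
#' the transparent measurement is immediately followed by the opaque one so
#' both see the same half-hourly drivers. Transparent chambers attenuate PAR
#' by 5%, so the flux inside a transparent chamber is evaluated at
#' `0.95 * PAR_outside`; the trace records the outside PAR. Branch traces
#' carry a leaf count; their source area is `leaf_count * mean_leaf_area`.
#'
#' @param scenario a [site_scenario()].
#' @param drivers driver series covering all campaign dates.
#' @param campaign_dates `Date` vector of campaign days; default
#'   [default_campaign_dates()].
#' @param closures_per_plot closures per plot and chamber type (>= 1).
#' @param analyzer_sd_ppm white analyzer noise, ppm (0 = noiseless).
#' @param seed integer seed.
#' @param chamber list of geometry defaults: `volume` (m3), `area` (m2) of
#'   ground chambers; `branch_volume`, `branch_area` of the branch cylinder;
#'   `mean_leaf_area` (m2 per leaf, campaign-level scalar);
#'   `t_excess` (chamber headspace warming, degC); `pressure` (Pa).
#' @return list with elements `traces` (`data.frame`: `trace_id`, `t` s,
#'   `co2` ppm) and `meta` (one row per closure: identifiers, geometry,
#'   environment, `true_flux_per_s` diagnostic).
#' @export
generate_campaign <- function(scenario, drivers,
                              campaign_dates = default_campaign_dates(scenario),
                              closures_per_plot = 4L,
                              analyzer_sd_ppm = 0.1,
                              seed = scenario$seed + 2L,
                              chamber = list()) {
  if (closures_per_plot < 1) stop("closures_per_plot must be >= 1")
  ch <- utils::modifyList(list(
    volume = 0.3, area = 0.75,
    branch_volume = pi * 0.095^2 * 0.40, branch_area = pi * 0.095^2,
    mean_leaf_area = 0.0012, t_excess = 1.5, pressure = 101325), chamber)
  campaign_dates <- as.Date(campaign_dates)
  dspan <- as.Date(range(drivers$timestamp), tz = "UTC")
  if (any(campaign_dates < dspan[1] | campaign_dates > dspan[2]))
    stop("campaign date outside driver span")
  slot_hours <- seq(5, 15.5, length.out = closures_per_plot)
  slot_hours <- round(slot_hours * 2) / 2      # snap to the driver grid
  drv_key <- as.numeric(drivers$timestamp)
  max_lai <- if (is.null(scenario$tree_lai)) 0 else max(scenario$tree_lai$lai)

  traces <- vector("list", 0); meta <- vector("list", 0)
  with_seed(seed, {
    for (d in as.list(campaign_dates)) {
      lai_d <- lai_at(scenario, d)
      for (mf in scenario$microforms) {
        branch <- identical(mf$name, "branch")
        plot_id <- paste0(scenario$site_id, "_", mf$name, "_p1")
        leaf_count <- if (branch)
          max(1L, as.integer(round(40 * lai_d / max(max_lai, 1e-9)))) else NA_integer_
        for (k in seq_along(slot_hours)) {
          step <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC") +
            slot_hours[k] * 3600
          i <- match(as.numeric(step), drv_key)
          if (is.na(i)) stop("campaign slot not on the driver grid")
          par_out <- drivers$par[i]
          t_air <- drivers$t_air[i]; t_soil <- drivers$t_soil[i]
          t_in <- t_air + ch$t_excess
          t_reco <- if (branch) t_air else t_soil
          reco_h <- lloyd_taylor(t_reco, mf$r_ref, mf$e0)
          gpp_h <- light_response(0.95 * par_out, mf$alpha, mf$gp_max)
          for (type in c("transparent", "opaque")) {
            # transparent first, opaque 7 min later, same half-hour
            start <- step + if (type == "transparent") 120 else 540
            flux_per_s <- if (type == "opaque") reco_h / 3600 else
              (gpp_h + reco_h) / 3600
            vol <- if (branch) ch$branch_volume else ch$volume
            src_area <- if (branch) leaf_count * ch$mean_leaf_area else ch$area
            geo_area <- if (branch) ch$branch_area else ch$area
            slope <- .flux_to_slope(flux_per_s, vol, src_area, t_in, ch$pressure)
            dur <- sample(120:180, 1L)
            tt <- 0:dur
            co2 <- 420 + stats::runif(1, -15, 15) + slope * tt +
              stats::rnorm(length(tt), 0, analyzer_sd_ppm)
            id <- sprintf("%s_%s_%s_s%d_%s", scenario$site_id, mf$name,
                          format(d, "%Y%m%d"), k, substr(type, 1, 2))
            traces[[length(traces) + 1L]] <-
              data.frame(trace_id = id, t = tt, co2 = co2)
            meta[[length(meta) + 1L]] <- data.frame(
              trace_id = id, plot_id = plot_id, site_id = scenario$site_id,
              microform = mf$name,
              chamber_type = if (branch && type == "transparent") "branch" else type,
              campaign_date = d, start_time = start, duration = dur,
              volume = vol, area = geo_area,
              t_air_inside = t_in, pressure = ch$pressure,
              par_outside = if (type == "opaque") NA_real_ else par_out,
              leaf_count = leaf_count,
              t_air = t_air, t_soil = t_soil,
              true_flux_per_s = flux_per_s)
          }
        }
      }
    }
  })
  list(traces = do.call(rbind, traces),
       meta = do.call(rbind, meta))
}

#' Default campaign schedule for a hydrological year
#'
#' Fourteen campaigns: monthly November-February, every 25 days from early
#' March through mid-October, starting shortly after the hydrological year
#' begins.
#'
#' @param scenario a [site_scenario()].
#' @return `Date` vector of length 14.
#' @export
default_campaign_dates <- function(scenario) {
  y0 <- scenario$hydro_year_start
  c(y0 + c(9, 39, 70, 101),                     # Nov-Feb, ~4-weekly
    seq(y0 + 124, by = 25, length.out = 10))    # Mar-Oct, ~3.5-weekly
}
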