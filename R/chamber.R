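# Closed-form OLS slope, intercept and r-squared for one window.
.ols <- function(t, y) {
  tm <- mean(t); ym <- mean(y)
  sxx <- sum((t - tm)^2)
  if (sxx == 0) stop("constant time vector in regression window")
  sxy <- sum((t - tm) * (y - ym))
  syy <- sum((y - ym)^2)
  slope <- sxy / sxx
  r2 <- if (syy == 0) 1 else (sxy^2) / (sxx * syy)
  list(slope = slope, intercept = ym - slope * tm, r_squared = r2)
}

#' Select the best regression window within a chamber trace
#'
#' Evaluates an ordinary-least-squares regression of concentration on time in
#' every candidate window of length `window_len` after an initial deadband,
#' stepping by `step` seconds, and returns the window with the highest
#' r-squared. Ties are broken by earliest start. A constant trace (zero
#' variance in concentration) has r-squared defined as 1, so the earliest
#' window wins.
#'
#' @param t time since closure, s (strictly increasing).
#' @param co2 CO2 mixing ratio, ppm.
#' @param window_len window length, s (default 60).
#' @param step window start increment, s (default 5).
#' @param deadband seconds discarded after closure (default 10).
#' @return list with `start`, `end` (s), `slope` (ppm s-1), `intercept`,
#'   `r_squared`, `n` (samples in the chosen window).
#' @export
select_window <- function(t, co2, window_len = 60, step = 5, deadband = 10) {
  stopifnot(length(t) == length(co2), length(t) >= 2)
  if (is.unsorted(t, strictly = TRUE)) stop("t must be strictly increasing")
  dur <- max(t) - min(t)
  if (dur < deadband + window_len)
    stop("trace too short for deadband + window_len")
  starts <- seq(min(t) + deadband, max(t) - window_len, by = step)
  best <- NULL
  for (s in starts) {
    in_w <- t >= s & t <= s + window_len
    if (sum(in_w) < 3) next
    fit <- .ols(t[in_w], co2[in_w])
    if (is.null(best) || fit$r_squared > best$r_squared) {
      best <- c(fit, list(start = s, end = s + window_len, n = sum(in_w)))
    }
  }
  if (is.null(best)) stop("no valid window found")
  best[c("start", "end", "slope", "intercept", "r_squared", "n")]
}

#' Convert a concentration slope into a CO2-C flux density
#'
#' Ideal-gas conversion for dynamic closed chambers:
#' `flux = slope * 1e-6 * p * V / (R * T * A) * M_C` with
#' `R = 8.314 J mol-1 K-1` and `M_C = 12.011 g mol-1`. The source area `A`
#' is the chamber ground area, or the enclosed leaf area
#' (`leaf_count * mean_leaf_area`) for branch chambers. The sign of the
#' slope is kept: positive = emission.
#'
#' @param slope concentration change, ppm s-1.
#' @param volume chamber volume, m3.
#' @param area chamber ground area, m2.
#' @param t_air_inside headspace air temperature, degC.
#' @param pressure air pressure, Pa.
#' @param leaf_count number of leaves in a branch chamber (`NA` otherwise).
#' @param mean_leaf_area mean area per leaf, m2; required with `leaf_count`.
#' @param branch logical; `TRUE` normalises to leaf area.
#' @return flux density, g CO2-C m-2 s-1.
#' @examples
#' compute_flux(0.1, volume = 0.3, area = 0.75,
#'              t_air_inside = 20, pressure = 101325)
#' @export
compute_flux <- function(slope, volume, area, t_air_inside, pressure,
                         leaf_count = NA, mean_leaf_area = NA,
                         branch = FALSE) {
  t_k <- t_air_inside + .T0K
  if (any(t_k <= 0)) stop("temperature must be above 0 K")
  if (any(volume <= 0) || any(area <= 0)) stop("volume and area must be > 0")
  src_area <- area
  if (branch) {
    if (anyNA(leaf_count)) stop("branch trace without leaf_count")
    if (anyNA(mean_leaf_area)) stop("branch trace without mean_leaf_area")
    src_area <- leaf_count * mean_leaf_area
    if (any(src_area <= 0)) stop("branch leaf area must be > 0")
  }
  slope * 1e-6 * (pressure * volume) / (.R_GAS * t_k * src_area) * .M_C
}

#' Minimal detectable flux of a chamber closure
#'
#' The smallest OLS slope distinguishable from zero given white analyzer
#' noise over an `n`-sample window spanning `window_len` seconds is
#' `slope_min = z * sd * sqrt(12 (n-1) / (n (n+1) window_len^2))` — `z` times
#' the exact standard error of the slope for equidistant samples. The MDF is
#' that slope run through [compute_flux()]; measured fluxes with magnitude
#' below it are set to zero and flagged.
#'
#' @param analyzer_sd_ppm analyzer noise standard deviation, ppm (>= 0).
#' @param n samples in the regression window (>= 3).
#' @param window_len window length, s.
#' @param z detection quantile (default 1.96, two-sided 95%).
#' @inheritParams compute_flux
#' @return minimal detectable flux, g CO2-C m-2 s-1 (>= 0).
#' @export
minimal_detectable_flux <- function(analyzer_sd_ppm, n, window_len,
                                    volume, area, t_air_inside, pressure,
                                    leaf_count = NA, mean_leaf_area = NA,
                                    branch = FALSE, z = 1.96) {
  if (analyzer_sd_ppm < 0) stop("analyzer_sd_ppm must be >= 0")
  if (any(n < 3)) stop("need at least 3 samples in the window")
  slope_min <- z * analyzer_sd_ppm *
    sqrt(12 * (n - 1) / (n * (n + 1) * window_len^2))
  abs(compute_flux(slope_min, volume, area, t_air_inside, pressure,
                   leaf_count, mean_leaf_area, branch))
}

#' Process chamber traces into flux observations
#'
#' For every closure: pick the best regression window ([select_window()]),
#' convert the slope into a flux density ([compute_flux()]), compute the
#' minimal detectable flux and zero fluxes below it, assign the flux type
#' (opaque -> Reco; transparent and branch -> NEE) and correct the recorded
#' PAR for the 5% transparent-chamber attenuation.
#'
#' @param traces long `data.frame` with `trace_id`, `t`, `co2`.
#' @param meta closure metadata, one row per `trace_id` (see
#'   [generate_campaign()] for the columns).
#' @param window_len,step,deadband moving-window settings, s.
#' @param analyzer_sd_ppm analyzer noise for the MDF, ppm.
#' @param mdf_z MDF detection quantile.
#' @param mean_leaf_area campaign-level mean leaf area, m2 per leaf.
#' @param par_attenuation fraction of outside PAR reaching the vegetation
#'   inside a transparent chamber (default 0.95).
#' @return `data.frame` of flux observations: identifiers, `flux_type`,
#'   `timestamp`, window diagnostics, `flux_per_s` (g CO2-C m-2 s-1), `flux`
#'   (g CO2-C m-2 30 min-1), `par` (corrected; `NA` for Reco), `t_air`,
#'   `t_soil`, `mdf`, `below_mdf`, `qc_pass` (all `TRUE`; see
#'   [qc_filter()]).
#' @export
process_traces <- function(traces, meta, window_len = 60, step = 5,
                           deadband = 10, analyzer_sd_ppm = 0.1,
                           mdf_z = 1.96, mean_leaf_area = 0.0012,
                           par_attenuation = 0.95) {
  idx <- split(seq_len(nrow(traces)), traces$trace_id)
  out <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    m <- meta[i, ]
    rows <- idx[[m$trace_id]]
    if (is.null(rows)) stop("no trace samples for ", m$trace_id)
    w <- select_window(traces$t[rows], traces$co2[rows],
                       window_len = window_len, step = step,
                       deadband = deadband)
    branch <- m$microform == "branch"
    f <- compute_flux(w$slope, m$volume, m$area, m$t_air_inside, m$pressure,
                      m$leaf_count, mean_leaf_area, branch = branch)
    mdf <- minimal_detectable_flux(analyzer_sd_ppm, w$n, window_len,
                                   m$volume, m$area, m$t_air_inside,
                                   m$pressure, m$leaf_count, mean_leaf_area,
                                   branch = branch, z = mdf_z)
    below <- abs(f) < mdf
    if (below) f <- 0
    flux_type <- if (m$chamber_type == "opaque") "Reco" else "NEE"
    out[[i]] <- data.frame(
      obs_id = m$trace_id, plot_id = m$plot_id, site_id = m$site_id,
      microform = m$microform, chamber_type = m$chamber_type,
      flux_type = flux_type, campaign_date = as.Date(m$campaign_date),
      timestamp = m$start_time,
      window_start = w$start, window_end = w$end,
      slope = w$slope, r_squared = w$r_squared,
      flux_per_s = f, flux = f * 1800,
      par = if (flux_type == "NEE" && !is.na(m$par_outside))
        par_attenuation * m$par_outside else NA_real_,
      t_air = m$t_air, t_soil = m$t_soil,
      mdf = mdf, below_mdf = below, qc_pass = TRUE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Remove illogically high morning fluxes
#'
#' Transparent-chamber (NEE) observations taken before the cutoff hour whose
#' flux magnitude exceeds `factor` times the plot's campaign median flux
#' magnitude are marked `qc_pass = FALSE`. All other observations pass
#' unchanged.
#'
#' @param obs flux observations from [process_traces()].
#' @param cutoff_hour local hour before which the rule applies (default 10).
#' @param factor multiple of the campaign median (default 3).
#' @return `obs` with updated `qc_pass`; the number of removals is reported
#'   via `message()`.
#' @export
qc_filter <- function(obs, cutoff_hour = 10, factor = 3) {
  if (nrow(obs) == 0) return(obs)
  hr <- as.POSIXlt(obs$timestamp, tz = "UTC")$hour
  is_nee <- obs$flux_type == "NEE"
  key <- paste(obs$plot_id, obs$campaign_date)
  med <- stats::ave(abs(obs$flux), key, is_nee,
                    FUN = function(x) stats::median(x))
  drop <- is_nee & hr < cutoff_hour & abs(obs$flux) > factor * med
  obs$qc_pass <- obs$qc_pass & !drop
  if (any(drop))
    message("qc_filter: removed ", sum(drop), " morning NEE observation(s)")
  obs
}

#' Derive GPP observations from paired NEE and Reco fluxes
#'
#' For every NEE observation, the nearest-in-time Reco observation from the
#' same plot within `max_dt` is subtracted: `GPP = NEE - Reco`. NEE
#' observations without a Reco candidate yield no GPP (absence is a valid
#' outcome, not an error).
#'
#' @param obs flux observations (NEE and Reco together) with `qc_pass`.
#' @param max_dt maximum time difference, s (default 2 h).
#' @return `data.frame` of GPP observations (`flux_type = "GPP"`, flux
#'   columns as in [process_traces()], `reco_obs_id` traceability column);
#'   zero rows if nothing can be paired.
#' @export
derive_gpp <- function(obs, max_dt = 2 * 3600) {
  obs <- obs[obs$qc_pass & !is.na(obs$flux), , drop = FALSE]
  nee <- obs[obs$flux_type == "NEE", , drop = FALSE]
  reco <- obs[obs$flux_type == "Reco", , drop = FALSE]
  out <- vector("list", nrow(nee))
  for (i in seq_len(nrow(nee))) {
    cand <- reco[reco$plot_id == nee$plot_id[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    dt <- abs(as.numeric(cand$timestamp) - as.numeric(nee$timestamp[i]))
    j <- which.min(dt)
    if (dt[j] > max_dt) next
    g <- nee[i, ]
    g$obs_id <- paste0(g$obs_id, "_gpp")
    g$flux_type <- "GPP"
    g$flux_per_s <- nee$flux_per_s[i] - cand$flux_per_s[j]
    g$flux <- g$flux_per_s * 1800
    g$reco_obs_id <- cand$obs_id[j]
    out[[i]] <- g
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0) {
    res <- nee[0, ]
    res$reco_obs_id <- character(0)
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
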