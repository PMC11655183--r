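#' Lloyd-Taylor temperature response of ecosystem respiration
#'
#' `Reco(T) = R_ref * exp(E0 * (1/(T_ref - T0) - 1/(T - T0)))` with
#' temperatures in Kelvin, `T_ref = 283.15 K` (10 degC) and the fixed
#' `T0 = 227.13 K` of the original parameterisation.
#'
#' @param t_c temperature, degC.
#' @param r_ref basal respiration at `T_ref`, g CO2-C m-2 h-1.
#' @param e0 temperature sensitivity, K (>= 0).
#' @param t_ref reference temperature, K.
#' @param t0 lower temperature limit, K.
#' @return respiration, g CO2-C m-2 h-1 (same units as `r_ref`).
#' @export
lloyd_taylor <- function(t_c, r_ref, e0, t_ref = 283.15, t0 = 227.13) {
  t_k <- t_c + .T0K
  if (any(t_k <= t0)) stop("temperature at or below the Lloyd-Taylor T0")
  r_ref * exp(e0 * (1 / (t_ref - t0) - 1 / (t_k - t0)))
}

#' Rectangular-hyperbola light response of gross photosynthesis
#'
#' `GPP(PAR) = -(alpha * PAR * GP_max) / (alpha * PAR + GP_max)`; returned
#' negative (uptake) under the atmospheric sign convention, 0 in the dark and
#' approaching `-GP_max` at saturating light.
#'
#' @param par photosynthetically active radiation, umol m-2 s-1 (>= 0).
#' @param alpha initial slope, g CO2-C per umol photons.
#' @param gp_max light-saturated gross photosynthesis, g CO2-C m-2 h-1.
#' @return GPP, g CO2-C m-2 h-1, <= 0.
#' @export
light_response <- function(par, alpha, gp_max) {
  if (any(par < 0)) stop("PAR must be >= 0")
  if (alpha <= 0 || gp_max <= 0) return(rep(0, length(par)))
  -(alpha * par * gp_max) / (alpha * par + gp_max)
}

# Lloyd-Taylor regressor x such that log(Reco) = log(R_ref) + E0 * x.
.lt_x <- function(t_c, t_ref = 283.15, t0 = 227.13) {
  1 / (t_ref - t0) - 1 / (t_c + .T0K - t0)
}

#' Fit the Lloyd-Taylor respiration model to one campaign's observations
#'
#' Nonlinear least squares of respiration against soil (or air) temperature.
#' Starting values come from the log-linearisation of the model; the nls fit
#' is constrained to non-negative parameters. When fewer than `min_n`
#' observations or less than `min_spread` degC of temperature spread are
#' available the fit is refused and flagged (`fallback = TRUE`) so that the
#' caller can substitute a neighbouring campaign.
#'
#' @param flux respiration observations, g CO2-C m-2 h-1 (positive).
#' @param t_c driving temperature, degC.
#' @param min_n minimum number of observations (default 3).
#' @param min_spread minimum temperature spread, degC (default 2).
#' @return list with `r_ref`, `e0`, `n`, `rmse`, `fallback`.
#' @export
fit_reco <- function(flux, t_c, min_n = 3L, min_spread = 2) {
  keep <- is.finite(flux) & is.finite(t_c)
  flux <- flux[keep]; t_c <- t_c[keep]
  n <- length(flux)
  if (n < min_n || diff(range(t_c)) < min_spread)
    return(list(r_ref = NA_real_, e0 = NA_real_, n = n, rmse = NA_real_,
                fallback = TRUE))
  x <- .lt_x(t_c)
  pos <- flux > 0
  if (sum(pos) >= 2 && diff(range(x[pos])) > 0) {
    cf <- stats::coef(stats::lm(log(flux[pos]) ~ x[pos]))
    start <- list(r_ref = max(exp(cf[[1]]), 1e-8), e0 = max(cf[[2]], 0))
  } else {
    start <- list(r_ref = max(mean(flux), 1e-8), e0 = 200)
  }
  fit <- tryCatch(
    stats::nls(flux ~ r_ref * exp(e0 * x), start = start,
               algorithm = "port", lower = c(r_ref = 0, e0 = 0),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) {
    p <- unlist(start)
    resid <- flux - p[["r_ref"]] * exp(p[["e0"]] * x)
    return(list(r_ref = p[["r_ref"]], e0 = p[["e0"]], n = n,
                rmse = sqrt(mean(resid^2)), fallback = FALSE))
  }
  p <- stats::coef(fit)
  list(r_ref = p[["r_ref"]], e0 = p[["e0"]], n = n,
       rmse = sqrt(mean(stats::resid(fit)^2)), fallback = FALSE)
}

#' Fit the rectangular-hyperbola light response to one campaign's GPP
#'
#' The fit is performed on flux magnitudes (`-GPP`); the sign is reapplied on
#' evaluation. Campaigns with no light (all `PAR = 0`) or no photosynthetic
#' signal yield a flagged zero-GPP model.
#'
#' @param gpp GPP observations, g CO2-C m-2 h-1 (<= 0 expected).
#' @param par PAR seen by the vegetation, umol m-2 s-1.
#' @param min_n minimum number of observations (default 3).
#' @return list with `alpha`, `gp_max`, `n`, `rmse`, `fallback`,
#'   `zero_model`.
#' @export
fit_gpp <- function(gpp, par, min_n = 3L) {
  keep <- is.finite(gpp) & is.finite(par)
  gpp <- gpp[keep]; par <- par[keep]
  n <- length(gpp)
  g <- pmax(-gpp, 0)                       # magnitudes
  if (n < min_n)
    return(list(alpha = NA_real_, gp_max = NA_real_, n = n, rmse = NA_real_,
                fallback = TRUE, zero_model = FALSE))
  lit <- par > 0
  if (!any(lit) || max(g[lit]) <= 0)
    return(list(alpha = 0, gp_max = 0, n = n, rmse = sqrt(mean(g^2)),
                fallback = FALSE, zero_model = TRUE))
  gp0 <- max(g) * 1.2
  low <- lit & par <= stats::quantile(par[lit], 0.5)
  alpha0 <- if (any(low) && max(par[low]) > 0) max(g[low]) / max(par[low]) else
    max(g[lit]) / max(par[lit])
  alpha0 <- max(alpha0, 1e-6)
  fit <- tryCatch(
    stats::nls(g ~ (alpha * par * gp_max) / (alpha * par + gp_max),
               start = list(alpha = alpha0, gp_max = gp0),
               algorithm = "port", lower = c(alpha = 0, gp_max = 0),
               control = stats::nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(alpha = alpha0, gp_max = gp0, n = n,
                rmse = sqrt(mean((g - (alpha0 * par * gp0) /
                                    (alpha0 * par + gp0))^2)),
                fallback = FALSE, zero_model = FALSE))
  p <- stats::coef(fit)
  list(alpha = p[["alpha"]], gp_max = p[["gp_max"]], n = n,
       rmse = sqrt(mean(stats::resid(fit)^2)),
       fallback = FALSE, zero_model = p[["gp_max"]] == 0)
}

#' Fit campaign-wise source models for every microform
#'
#' Groups flux observations by microform and campaign date, fits [fit_reco()]
#' to the opaque (Reco) fluxes and [fit_gpp()] to the derived GPP fluxes, and
#' fills refused fits from the nearest successful campaign of the same
#' microform (flagged in the output).
#'
#' Respiration of ground microforms is driven by soil temperature; the branch
#' source, whose environment is only measured at chamber level, is driven by
#' air temperature.
#'
#' @param obs flux observations as returned by [process_traces()] /
#'   [qc_filter()]; only rows with `qc_pass` are used.
#' @param gpp_obs GPP observations from [derive_gpp()].
#' @return `data.frame` (one row per microform x campaign) with columns
#'   `microform`, `campaign_date`, `r_ref`, `e0`, `alpha`, `gp_max`,
#'   `n_reco`, `n_gpp`, `rmse_reco`, `rmse_gpp`, `fallback_reco`,
#'   `fallback_gpp`.
#' @export
fit_campaigns <- function(obs, gpp_obs) {
  obs <- obs[obs$qc_pass & !obs$below_mdf, , drop = FALSE]
  reco <- obs[obs$flux_type == "Reco", , drop = FALSE]
  mfs <- sort(unique(c(reco$microform, gpp_obs$microform)))
  dates <- sort(unique(as.Date(c(reco$campaign_date, gpp_obs$campaign_date))))
  rows <- list()
  for (mf in mfs) {
    branch <- identical(mf, "branch")
    for (d in as.list(dates)) {
      r <- reco[reco$microform == mf & as.Date(reco$campaign_date) == d, ]
      g <- gpp_obs[gpp_obs$microform == mf &
                     as.Date(gpp_obs$campaign_date) == d, ]
      drv_t <- if (branch) r$t_air else r$t_soil
      fr <- fit_reco(r$flux_per_s * 3600, drv_t)
      fg <- fit_gpp(g$flux_per_s * 3600, g$par)
      rows[[length(rows) + 1L]] <- data.frame(
        microform = mf, campaign_date = as.Date(d),
        r_ref = fr$r_ref, e0 = fr$e0, alpha = fg$alpha, gp_max = fg$gp_max,
        n_reco = fr$n, n_gpp = fg$n, rmse_reco = fr$rmse, rmse_gpp = fg$rmse,
        fallback_reco = fr$fallback, fallback_gpp = fg$fallback)
    }
  }
  out <- do.call(rbind, rows)
  # nearest-campaign substitution for refused fits, per microform
  for (mf in mfs) {
    i <- which(out$microform == mf)
    for (cols in list(c("r_ref", "e0", "fallback_reco"),
                      c("alpha", "gp_max", "fallback_gpp"))) {
      bad <- i[out[[cols[3]]][i] | !is.finite(out[[cols[1]]][i])]
      good <- setdiff(i, bad)
      if (length(bad) && length(good)) {
        for (b in bad) {
          nearest <- good[which.min(abs(as.numeric(
            out$campaign_date[good] - out$campaign_date[b])))]
          out[b, cols[1:2]] <- out[nearest, cols[1:2]]
          out[b, cols[3]] <- TRUE
        }
      } else if (length(bad)) {
        # no campaign of this microform ever fit: honest zero model, flagged
        message("fit_campaigns: no usable ", cols[1], " fit for ", mf,
                "; zero model substituted")
        out[bad, cols[1:2]] <- 0
        out[bad, cols[3]] <- TRUE
      }
    }
  }
  rownames(out) <- NULL
  out
}

#' Reconstruct daily source fluxes over a span from campaign models
#'
#' Model parameters are linearly interpolated in time between campaign
#' midpoints (held constant before the first and after the last campaign),
#' evaluated half-hourly from the driver series and integrated to daily sums.
#' Ground respiration is driven by soil temperature, branch respiration by
#' air temperature; the branch source is reported per m2 of leaf.
#'
#' @param models campaign model table from [fit_campaigns()].
#' @param drivers driver series from [generate_drivers()] (gap-free).
#' @param span `Date` vector of length 2, first and last day (inclusive),
#'   typically the hydrological year.
#' @param interpolation `"linear"` (default) or `"constant"` (per-campaign
#'   blocks, nearest campaign).
#' @return `data.frame` with columns `date`, `microform`, `gpp`, `reco`,
#'   `nee` in g CO2-C m-2 of source d-1; `nee = gpp + reco` exactly.
#' @export
daily_reconstruct <- function(models, drivers, span,
                              interpolation = c("linear", "constant")) {
  interpolation <- match.arg(interpolation)
  span <- as.Date(span)
  stopifnot(length(span) == 2L, span[1] <= span[2])
  day <- as.Date(drivers$timestamp, tz = "UTC")
  sel <- day >= span[1] & day <= span[2]
  if (!all(seq(span[1], span[2], by = 1) %in% unique(day[sel])))
    stop("drivers do not cover the requested span")
  drv <- drivers[sel, , drop = FALSE]
  day <- day[sel]
  if (anyNA(drv[c("par", "t_air", "t_soil")]))
    stop("driver series contains gaps")
  tnum <- as.numeric(drv$timestamp)
  out <- list()
  for (mf in unique(models$microform)) {
    m <- models[models$microform == mf, , drop = FALSE]
    m <- m[order(m$campaign_date), , drop = FALSE]
    mid <- as.numeric(as.POSIXct(paste(m$campaign_date, "12:00:00"), tz = "UTC"))
    ip <- function(v) {
      if (nrow(m) == 1L) return(rep(v, length(tnum)))
      method <- if (interpolation == "linear") "linear" else "constant"
      if (interpolation == "constant") {
        # nearest campaign block: switch halfway between campaigns
        edges <- (mid[-1] + mid[-length(mid)]) / 2
        idx <- findInterval(tnum, edges) + 1L
        return(v[idx])
      }
      stats::approx(mid, v, xout = tnum, method = method, rule = 2)$y
    }
    r_ref <- ip(m$r_ref); e0 <- ip(m$e0)
    alpha <- ip(m$alpha); gp_max <- ip(m$gp_max)
    t_drv <- if (identical(mf, "branch")) drv$t_air else drv$t_soil
    reco_hh <- r_ref * exp(e0 * .lt_x(t_drv)) / 2      # g C m-2 30min-1
    denom <- alpha * drv$par + gp_max
    gpp_hh <- ifelse(denom > 0, -(alpha * drv$par * gp_max) / denom, 0) / 2
    reco_d <- tapply(reco_hh, day, sum)
    gpp_d <- tapply(gpp_hh, day, sum)
    out[[mf]] <- data.frame(
      date = as.Date(names(reco_d)), microform = mf,
      gpp = as.numeric(gpp_d), reco = as.numeric(reco_d),
      nee = as.numeric(gpp_d) + as.numeric(reco_d))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
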