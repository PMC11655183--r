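# Shared fixtures and independent oracles, built in code at test time.

# Exhaustive moving-window oracle: lm() in every candidate window, maximum
# r-squared, earliest start on ties. Independent of select_window's internals.
oracle_window <- function(t, co2, window_len = 60, step = 5, deadband = 10) {
  starts <- seq(min(t) + deadband, max(t) - window_len, by = step)
  best <- NULL
  for (s in starts) {
    in_w <- t >= s & t <= s + window_len
    if (sum(in_w) < 3) next
    fit <- stats::lm(co2[in_w] ~ t[in_w])
    r2 <- summary(fit)$r.squared
    if (is.nan(r2)) r2 <- 1      # zero-variance window: perfect fit
    if (is.null(best) || r2 > best$r_squared)
      best <- list(start = s, slope = unname(stats::coef(fit)[2]),
                   r_squared = r2)
  }
  best
}

# Random chamber-like trace: piecewise slopes plus noise.
random_trace <- function(dur = NULL) {
  if (is.null(dur)) dur <- sample(120:180, 1)
  t <- 0:dur
  brk <- sample(30:(dur - 30), 1)
  s1 <- stats::runif(1, -0.05, 0.2); s2 <- stats::runif(1, -0.05, 0.2)
  co2 <- 420 + ifelse(t < brk, s1 * t, s1 * brk + s2 * (t - brk)) +
    stats::rnorm(length(t), 0, 0.3)
  list(t = t, co2 = co2)
}

# Minimal flux-observation rows for pairing tests.
make_obs <- function(microform, flux_type, timestamp, flux, par = NA,
                     t_air = 10, t_soil = 8, plot_id = NULL,
                     site_id = "open") {
  n <- max(lengths(list(microform, timestamp, flux)))
  data.frame(
    obs_id = paste0("o", seq_len(n), "_", microform),
    plot_id = if (is.null(plot_id)) paste0(site_id, "_", microform, "_p1")
    else plot_id,
    site_id = site_id, microform = microform, chamber_type = "x",
    flux_type = flux_type,
    campaign_date = as.Date(as.POSIXct(timestamp, tz = "UTC")),
    timestamp = as.POSIXct(timestamp, tz = "UTC"),
    window_start = 10, window_end = 70, slope = 0, r_squared = 1,
    flux_per_s = flux / 1800, flux = flux, par = par,
    t_air = t_air, t_soil = t_soil, mdf = 0, below_mdf = FALSE,
    qc_pass = TRUE)
}

# A two-source toy scenario with light bookkeeping for partition tests.
toy_scenario <- function() {
  site_scenario("toy", list(
    microform_spec("hollow", 0.4, r_ref = 0.05, e0 = 100,
                   alpha = 0.001, gp_max = 0.2),
    microform_spec("hummock", 0.6, r_ref = 0.10, e0 = 150,
                   alpha = 0.001, gp_max = 0.3)),
    seed = 42L)
}
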