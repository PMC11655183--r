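test_that("select_window: exact slopes, tie-break, oracle agreement", {
  t <- 0:150
  lin <- 400 + 0.05 * t
  w <- select_window(t, lin)
  expect_equal(w$slope, 0.05)
  expect_equal(w$start, 10)            # earliest window on ties
  expect_equal(w$r_squared, 1)
  # piecewise trace: compare against exhaustive lm() enumeration
  pw <- 400 + ifelse(t < 60, 0.10 * t, 0.10 * 60 + 0.02 * (t - 60))
  set.seed(1); pw <- pw + rnorm(length(t), 0, 0.05)
  got <- select_window(t, pw, window_len = 60, step = 5, deadband = 10)
  ref <- oracle_window(t, pw, window_len = 60, step = 5, deadband = 10)
  expect_equal(got$start, ref$start)
  expect_equal(got$slope, ref$slope, tolerance = 1e-10)
  expect_error(select_window(0:50, rnorm(51)), "too short")
  expect_error(select_window(c(0, 0, 1:149), rep(1, 151)), "increasing")
})

test_that("select_window matches the exhaustive oracle on random traces", {
  set.seed(202)
  for (i in 1:30) {
    tr <- random_trace()
    got <- select_window(tr$t, tr$co2)
    ref <- oracle_window(tr$t, tr$co2)
    expect_equal(got$start, ref$start)
    expect_equal(got$slope, ref$slope, tolerance = 1e-9)
  }
})

test_that("compute_flux implements the ideal-gas conversion", {
  # hand-evaluated oracle: slope 0.1 ppm/s, V 0.3 m3, A 0.75 m2, 20 degC
  expected <- 0.1e-6 * (101325 * 0.3) / (8.314 * 293.15 * 0.75) * 12.011
  expect_equal(compute_flux(0.1, 0.3, 0.75, 20, 101325), expected)
  expect_equal(expected, 2.0e-5, tolerance = 2e-3)
  expect_equal(compute_flux(0, 0.3, 0.75, 20, 101325), 0)
  # doubling the source area halves the flux
  expect_equal(compute_flux(0.1, 0.3, 1.5, 20, 101325), expected / 2)
  # branch traces normalise to leaf area and need a leaf count
  expect_error(compute_flux(0.1, 0.01, 0.03, 20, 101325, leaf_count = NA,
                            mean_leaf_area = 0.0012, branch = TRUE),
               "leaf_count")
  lf <- compute_flux(0.1, 0.01, 0.03, 20, 101325, leaf_count = 25,
                     mean_leaf_area = 0.0012, branch = TRUE)
  expect_equal(lf, 0.1e-6 * (101325 * 0.01) /
                 (8.314 * 293.15 * (25 * 0.0012)) * 12.011)
})

test_that("minimal detectable flux: zero noise, monotonicity, errors", {
  geo <- list(v = 0.3, a = 0.75, t = 20, p = 101325)
  mdf <- function(sd, n, L) minimal_detectable_flux(sd, n, L, geo$v, geo$a,
                                                    geo$t, geo$p)
  expect_equal(mdf(0, 61, 60), 0)
  # doubling the window (and its 1-Hz sample count) shrinks the MDF
  expect_lt(mdf(0.3, 121, 120), mdf(0.3, 61, 60))
  # non-decreasing in analyzer noise
  sds <- seq(0, 1, by = 0.1)
  vals <- vapply(sds, function(s) mdf(s, 61, 60), numeric(1))
  expect_true(all(diff(vals) >= 0))
  expect_error(mdf(0.3, 2, 60), "3 samples")
  expect_error(minimal_detectable_flux(-1, 61, 60, geo$v, geo$a, geo$t,
                                       geo$p), "analyzer_sd_ppm")
})

test_that("process_traces zeroes sub-MDF fluxes and keeps strong ones", {
  sc <- open_site_scenario(seed = 21L)
  drv <- generate_drivers(sc, as.Date("2021-06-01"), as.Date("2021-06-03"))
  camp <- generate_campaign(sc, drv, campaign_dates = as.Date("2021-06-02"),
                            closures_per_plot = 2, analyzer_sd_ppm = 0)
  obs <- process_traces(camp$traces, camp$meta, analyzer_sd_ppm = 0)
  expect_true(all(!obs$below_mdf))
  # with huge analyzer sd assumed in the MDF, everything is zeroed
  obs2 <- process_traces(camp$traces, camp$meta, analyzer_sd_ppm = 1e3)
  expect_true(all(obs2$below_mdf))
  expect_true(all(obs2$flux == 0))
  # opaque traces from Reco-only sources give non-negative fluxes
  expect_true(all(obs$flux_per_s[obs$flux_type == "Reco"] >= 0))
  # 5% PAR attenuation correction
  m <- camp$meta[camp$meta$chamber_type != "opaque", ]
  o <- obs[match(m$trace_id, obs$obs_id), ]
  expect_equal(o$par, 0.95 * m$par_outside)
})

test_that("qc_filter removes only illogical high morning NEE fluxes", {
  empty <- make_obs("hummock", "NEE", "2021-06-01 08:00", -0.1, 500)[0, ]
  expect_equal(nrow(qc_filter(empty)), 0)
  ts <- as.POSIXct("2021-06-01 08:00", tz = "UTC") + (0:3) * 3600
  same <- make_obs("hummock", "NEE", ts, flux = rep(-0.1, 4), par = 500)
  expect_true(all(qc_filter(same, factor = 1.5)$qc_pass))
  spiky <- same; spiky$flux[1] <- -0.5   # 5x the plot median, at 08:00
  out <- suppressMessages(qc_filter(spiky, cutoff_hour = 10, factor = 3))
  expect_equal(out$qc_pass, c(FALSE, TRUE, TRUE, TRUE))
})

test_that("derive_gpp subtracts the nearest-in-time Reco within 2 h", {
  t0 <- as.POSIXct("2021-06-01 10:00", tz = "UTC")
  nee <- make_obs("hummock", "NEE", t0, flux = -0.10, par = 800)
  reco <- make_obs("hummock", "Reco", c(t0 + 90 * 60, t0 + 30 * 60),
                   flux = c(0.09, 0.06))
  g <- derive_gpp(rbind(nee, reco))
  expect_equal(nrow(g), 1)
  expect_equal(g$flux, -0.16)                       # -0.10 - 0.06
  expect_equal(g$reco_obs_id, reco$obs_id[2])       # 30-min candidate wins
  # no Reco within 2 h -> no GPP
  far <- make_obs("hummock", "Reco", t0 + 3 * 3600, flux = 0.06)
  expect_equal(nrow(derive_gpp(rbind(nee, far))), 0)
  # different plot's Reco is never used
  other <- make_obs("hollow", "Reco", t0, flux = 0.06)
  expect_equal(nrow(derive_gpp(rbind(nee, other))), 0)
})
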