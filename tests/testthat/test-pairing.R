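test_that("pairing thresholds validate", {
  th <- pairing_thresholds()
  expect_equal(th$par_threshold, 150)
  expect_equal(th$ec_tolerance, 4 * 86400)
  expect_error(pairing_thresholds(d_par = 0), "positive")
})

# PAR values comfortably above the 150 W m-2 floor (x 4.57 umol/J).
PAR_HI <- 1000

test_that("build_groups forms hummock-hollow pairs under the thresholds", {
  sc <- open_site_scenario()
  t0 <- as.POSIXct("2021-06-01 11:00", tz = "UTC")
  hum <- make_obs("hummock", "NEE", t0, flux = -0.2, par = PAR_HI)
  hol <- make_obs("hollow", "NEE", t0 + 1800, flux = -0.1, par = PAR_HI * 0.9)
  g <- build_groups(rbind(hum, hol), sc)
  expect_equal(nrow(g), 1)
  expect_equal(g$value, 0.435 * -0.2 + 0.565 * -0.1)
  mem <- attr(g, "members")
  expect_equal(sum(mem$weight * mem$flux), g$value)
  # a 25% PAR difference blocks NEE pairing
  hol25 <- make_obs("hollow", "NEE", t0 + 1800, flux = -0.1,
                    par = PAR_HI / 1.25 * (1 - 0.25 / 2))
  expect_equal(nrow(build_groups(rbind(hum, hol25), sc)), 0)
  # air temperature gate
  hol_t <- hol; hol_t$t_air <- hum$t_air + 3
  expect_equal(nrow(build_groups(rbind(hum, hol_t), sc)), 0)
  # time gate
  hol_far <- make_obs("hollow", "NEE", t0 + 2 * 3600, flux = -0.1,
                      par = PAR_HI)
  expect_equal(nrow(build_groups(rbind(hum, hol_far), sc)), 0)
})

test_that("smallest PAR difference wins; observations are not reused", {
  sc <- open_site_scenario()
  t0 <- as.POSIXct("2021-06-01 11:00", tz = "UTC")
  hum <- make_obs("hummock", "NEE", t0, flux = -0.2, par = PAR_HI)
  hols <- make_obs("hollow", "NEE", rep(t0, 3), flux = c(-0.1, -0.11, -0.12),
                   par = PAR_HI * c(0.95, 0.92, 0.85))
  g <- build_groups(rbind(hum, hols), sc)
  expect_equal(nrow(g), 1)
  mem <- attr(g, "members")
  expect_equal(mem$obs_id[mem$microform == "hollow"], hols$obs_id[1])
  # Reco pairing by smallest time difference
  humr <- make_obs("hummock", "Reco", t0, flux = 0.1)
  holr <- make_obs("hollow", "Reco", c(t0 + 40 * 60, t0 + 10 * 60),
                   flux = c(0.05, 0.06))
  gr <- build_groups(rbind(humr, holr), sc)
  memr <- attr(gr, "members")
  expect_equal(memr$obs_id[memr$microform == "hollow"], holr$obs_id[2])
  # one-to-one: two hummocks, one hollow -> a single group
  hum2 <- make_obs("hummock", "NEE", c(t0, t0 + 600),
                   flux = c(-0.2, -0.25), par = c(PAR_HI, PAR_HI * 0.97))
  g2 <- build_groups(rbind(hum2, hols[1, ]), sc)
  expect_equal(nrow(g2), 1)
})

test_that("tree-site groups combine T and nT pairs and add the branch", {
  sc <- tree_site_scenario()
  t0 <- as.POSIXct("2021-07-01 11:00", tz = "UTC")
  obs <- rbind(
    make_obs("T_hummock", "NEE", t0, -0.2, PAR_HI, site_id = "tree"),
    make_obs("T_hollow", "NEE", t0 + 600, -0.1, PAR_HI, site_id = "tree"),
    make_obs("nT_hummock", "NEE", t0 + 1200, -0.15, PAR_HI, site_id = "tree"),
    make_obs("nT_hollow", "NEE", t0 + 1800, -0.08, PAR_HI, site_id = "tree"),
    make_obs("branch", "NEE", t0 + 900, -0.3, PAR_HI, site_id = "tree"))
  g <- build_groups(obs, sc)
  expect_equal(nrow(g), 1)
  expect_true(g$has_branch)
  mem <- attr(g, "members")
  expect_equal(nrow(mem), 5)
  w_br <- mem$weight[mem$microform == "branch"]
  expect_equal(w_br, lai_at(sc, as.Date(t0)))
  expect_equal(sum(mem$weight * mem$flux), g$value)
  # strict mode drops a vegetation-period group without a branch
  expect_equal(nrow(build_groups(obs[1:4, ], sc, strict = TRUE)), 0)
  g_len <- build_groups(obs[1:4, ], sc, strict = FALSE)
  expect_equal(nrow(g_len), 1)
  expect_false(g_len$has_branch)
})

test_that("match_ec obeys tolerances and minimises the right metric", {
  t0 <- as.POSIXct("2021-06-10 11:00", tz = "UTC")
  grp <- data.frame(group_id = "g1", site_id = "open", flux_type = "NEE",
                    timestamp = t0, par = PAR_HI, t_air = 15, t_soil = 12,
                    value = -0.2, n_members = 2, has_branch = FALSE)
  ec_row <- function(ts, par, nee = -0.25) data.frame(
    timestamp = ts, nee = nee, gpp = nee - 0.05, reco = 0.05,
    nee_obs = nee, qc_flag = 0L, gapfilled = FALSE, par = par)
  # identical timestamp and PAR: matched at distance 0
  p <- match_ec(grp, ec_row(t0, PAR_HI))
  expect_equal(nrow(p), 1)
  expect_equal(p$ec_timestamp, t0)
  # only candidate 5 days away: unmatched
  expect_equal(suppressMessages(
    nrow(match_ec(grp, ec_row(t0 + 5 * 86400, PAR_HI)))), 0)
  # time-of-day gate: same |dt| but 3 h off in daytime
  expect_equal(suppressMessages(
    nrow(match_ec(grp, ec_row(t0 + 3 * 3600, PAR_HI)))), 0)
  # smaller PAR difference wins even when further away in time
  ec2 <- rbind(ec_row(t0 + 3 * 86400, PAR_HI * 0.97),
               ec_row(t0 + 86400, PAR_HI * 0.99))
  p2 <- match_ec(grp, ec2)
  expect_equal(p2$ec_timestamp, t0 + 86400)
  # qc != 0 or gap-filled records are never used
  bad <- ec_row(t0, PAR_HI); bad$qc_flag <- 1L
  expect_equal(suppressMessages(nrow(match_ec(grp, bad))), 0)
})

test_that("compare_methods: identity, offset, known correlation", {
  t0 <- as.POSIXct("2021-06-10 11:00", tz = "UTC")
  mkpairs <- function(ch, ec) data.frame(
    group_id = paste0("g", seq_along(ch)), site_id = "open",
    flux_type = "NEE", timestamp = t0, par = PAR_HI, t_air = 15,
    t_soil = 12, value = ch, n_members = 2, has_branch = FALSE,
    ec_timestamp = t0, ec_value = ec, ec_par = PAR_HI)
  x <- seq(-0.3, 0.3, length.out = 20)
  rep1 <- suppressWarnings(compare_methods(mkpairs(x, x)))  # perfect fit
  expect_equal(rep1$slope, 1)
  expect_equal(rep1$intercept, 0, tolerance = 1e-12)
  expect_equal(rep1$r_squared, 1)
  rep2 <- suppressWarnings(compare_methods(mkpairs(x + 0.05, x)))
  expect_equal(rep2$slope, 1)
  expect_equal(rep2$intercept, 0.05)
  expect_equal(rep2$offset, 0.05)
  expect_error(compare_methods(mkpairs(x[1:2], x[1:2])), "at least 3")
  # synthetic pairs with true correlation 0.8: r^2 inside a Monte-Carlo
  # interval for rho^2 = 0.64 computed with an independent simulation
  set.seed(404)
  n <- 200
  z <- rnorm(n); e <- rnorm(n)
  ec <- z
  ch <- 0.8 * z + sqrt(1 - 0.64) * e
  r2 <- compare_methods(mkpairs(ch, ec))$r_squared
  sim <- replicate(500, {
    zz <- rnorm(n); cc <- 0.8 * zz + sqrt(1 - 0.64) * rnorm(n)
    stats::cor(zz, cc)^2
  })
  ci <- stats::quantile(sim, c(0.005, 0.995))
  expect_gt(r2, ci[1])
  expect_lt(r2, ci[2])
})

test_that("rainbow test flags curvature and passes linear data", {
  set.seed(11)
  x <- seq(-1, 1, length.out = 60)
  y_lin <- 2 + 3 * x + rnorm(60, 0, 0.1)
  y_quad <- 2 + 3 * x + 4 * x^2 + rnorm(60, 0, 0.1)
  expect_gt(rainbow_test(x, y_lin)$p_value, 0.01)
  expect_lt(rainbow_test(x, y_quad)$p_value, 1e-4)
})
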