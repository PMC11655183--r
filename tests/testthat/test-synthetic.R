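test_that("scenario constructors validate their invariants", {
  expect_error(microform_spec("h", 1.2, 0.1, 100, 0.001, 0.2), "areal_share")
  expect_error(microform_spec("h", 0.5, -0.1, 100, 0.001, 0.2), "r_ref")
  expect_error(site_scenario("s", list(
    microform_spec("a", 0.5, 0.1, 100, 0.001, 0.2),
    microform_spec("b", 0.4, 0.1, 100, 0.001, 0.2))), "sum to 1")
  bad_lai <- data.frame(date = as.Date(c("2021-06-01", "2021-05-01")),
                        lai = c(0.5, 0.2))
  expect_error(site_scenario("s", list(
    microform_spec("a", 1, 0.1, 100, 0.001, 0.2)), tree_lai = bad_lai),
    "increasing")
})

test_that("drivers: night PAR, determinism, configured annual mean", {
  sc <- open_site_scenario(seed = 11L)
  drv <- generate_drivers(sc)
  expect_equal(nrow(drv), 17520)
  expect_true(all(diff(as.numeric(drv$timestamp)) == 1800))
  midnight <- as.POSIXlt(drv$timestamp, tz = "UTC")$hour == 0
  expect_true(all(drv$par[midnight] == 0))
  expect_true(all(drv$par >= 0))
  drv2 <- generate_drivers(sc)
  expect_identical(drv, drv2)
  # annual mean of the generated air temperature stays near the configured
  # 9.9 degC (the sinusoids integrate to ~0 over the year, the AR(1) noise
  # mean shrinks as 1/sqrt(n))
  expect_lt(abs(mean(drv$t_air) - 9.9), 0.3)
  expect_error(generate_drivers(sc, as.Date("2021-01-02"),
                                as.Date("2021-01-01")), "empty")
})

test_that("true_flux follows the closed-form models", {
  sc <- open_site_scenario()
  drv <- generate_drivers(sc, as.Date("2020-11-01"), as.Date("2020-11-02"))
  mf <- sc$microforms$hummock
  tf <- true_flux(mf, drv)
  expect_true(all(tf$gpp[drv$par == 0] == 0))
  expect_equal(tf$nee, tf$gpp + tf$reco)
  dark <- microform_spec("hummock", 0.435, r_ref = 0.1, e0 = 200, alpha = 0,
                         gp_max = 0.5)
  expect_true(all(true_flux(dark, drv)$gpp == 0))
  # T = T_ref = 10 degC gives exactly R_ref per hour, halved per 30-min step
  drv10 <- drv[1:2, ]; drv10$t_soil <- 10; drv10$par <- 0
  expect_equal(true_flux(mf, drv10)$reco, rep(mf$r_ref / 2, 2))
  drv_bad <- drv; drv_bad$par[5] <- -1
  expect_error(true_flux(mf, drv_bad), "PAR")
})

test_that("generate_ec conserves the weighted truth and handles gaps", {
  sc <- open_site_scenario(seed = 5L)
  drv <- generate_drivers(sc)
  ec0 <- generate_ec(sc, drv, noise_sd = 0, gap_fraction = 0)
  truth <- Reduce(`+`, lapply(sc$microforms, function(m)
    m$areal_share * true_flux(m, drv)$nee))
  expect_lt(max(abs(ec0$nee - truth)), 1e-9)
  expect_true(all(ec0$reco >= 0) && all(ec0$gpp <= 0))
  expect_lt(max(abs(ec0$nee - (ec0$gpp + ec0$reco))), 1e-9)
  ec <- generate_ec(sc, drv, noise_sd = 0.02, gap_fraction = 0.2, seed = 9L)
  expect_gt(mean(ec$gapfilled), 0.18)
  expect_lt(mean(ec$gapfilled), 0.22)
  expect_true(all(is.na(ec$nee_obs[ec$gapfilled])))
  expect_identical(ec, generate_ec(sc, drv, noise_sd = 0.02,
                                   gap_fraction = 0.2, seed = 9L))
  expect_error(generate_ec(sc, drv, gap_fraction = 1), "gap_fraction")
})

test_that("an open scenario without a branch ignores the LAI series", {
  mfs <- list(microform_spec("hollow", 0.5, 0.05, 100, 0.001, 0.2),
              microform_spec("hummock", 0.5, 0.10, 150, 0.001, 0.3))
  lai <- data.frame(date = as.Date(c("2021-05-01", "2021-07-01")),
                    lai = c(0.3, 1))
  sc1 <- site_scenario("s", mfs, seed = 3L)
  sc2 <- site_scenario("s", mfs, tree_lai = lai, seed = 3L)
  drv <- generate_drivers(sc1, as.Date("2021-05-01"), as.Date("2021-05-03"))
  expect_equal(generate_ec(sc1, drv, 0, 0, seed = 1)$nee,
               generate_ec(sc2, drv, 0, 0, seed = 1)$nee)
})

test_that("generate_campaign: counts, determinism, errors", {
  open <- open_site_scenario(seed = 1L)
  tree <- tree_site_scenario(seed = 2L)
  drv_o <- generate_drivers(open)
  drv_t <- generate_drivers(tree)
  co <- generate_campaign(open, drv_o, analyzer_sd_ppm = 0)
  ct <- generate_campaign(tree, drv_t, analyzer_sd_ppm = 0)
  # 14 campaigns x 7 variants (2 open + 5 tree) x 4 closures x 2 types
  expect_equal(nrow(co$meta) + nrow(ct$meta), 784)
  expect_true(all(co$meta$duration >= 120 & co$meta$duration <= 180))
  expect_true(all(is.na(co$meta$par_outside[co$meta$chamber_type == "opaque"])))
  expect_true(all(ct$meta$leaf_count[ct$meta$microform == "branch"] >= 1))
  co2 <- generate_campaign(open, drv_o, analyzer_sd_ppm = 0)
  expect_identical(co, co2)
  expect_error(generate_campaign(open, drv_o,
                                 campaign_dates = as.Date("2025-01-01")),
               "outside driver span")
})
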