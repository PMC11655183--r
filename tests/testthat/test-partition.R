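test_that("ec_daily sums complete days and rejects incomplete ones", {
  ts <- seq(as.POSIXct("2021-06-01 00:00", tz = "UTC"), by = 1800,
            length.out = 96)
  zero <- data.frame(timestamp = ts, nee = 0, gpp = 0, reco = 0)
  d0 <- ec_daily(zero)
  expect_equal(d0$nee, c(0, 0))
  const <- data.frame(timestamp = ts, nee = -0.01, gpp = -0.01, reco = 0)
  expect_equal(ec_daily(const)$nee, c(-0.48, -0.48))
  set.seed(8)
  rnd <- data.frame(timestamp = ts, gpp = -runif(96), reco = runif(96))
  rnd$nee <- rnd$gpp + rnd$reco
  got <- ec_daily(rnd)
  # brute-force accumulation oracle
  expect_equal(got$gpp[1], sum(rnd$gpp[1:48]))
  expect_equal(got$reco[2], sum(rnd$reco[49:96]))
  expect_error(ec_daily(zero[-1, ]), "incomplete")
})

test_that("partition_day distributes EC fluxes by relative weights", {
  sc <- toy_scenario()
  day <- function(gpp, reco) data.frame(
    date = as.Date("2021-06-01"), microform = c("hollow", "hummock"),
    gpp = gpp, reco = reco, nee = gpp + reco)
  # symmetry: equal areal share x equal density -> equal halves
  sc_eq <- site_scenario("eq", list(
    microform_spec("hollow", 0.5, 0.05, 100, 0.001, 0.2),
    microform_spec("hummock", 0.5, 0.05, 100, 0.001, 0.2)))
  p <- partition_day(day(c(-1, -1), c(2, 2)), sc_eq, 0, -3, 2)
  expect_equal(p$reco, c(1, 1))
  expect_equal(p$gpp, c(-1.5, -1.5))
  expect_equal(p$nee, p$gpp + p$reco)
  # single source takes 100%
  sc1 <- site_scenario("one", list(
    microform_spec("only", 1, 0.05, 100, 0.001, 0.2)))
  d1 <- data.frame(date = as.Date("2021-06-01"), microform = "only",
                   gpp = -1, reco = 2, nee = 1)
  p1 <- partition_day(d1, sc1, 0, -4, 3)
  expect_equal(p1$rel_reco, 1)
  expect_equal(p1$reco, 3)
  expect_equal(p1$gpp, -4)
  # weights {2, 3, 5} with EC Reco 1 -> contributions {0.2, 0.3, 0.5}
  sc3 <- site_scenario("three", list(
    microform_spec("a", 0.2, 0.05, 100, 0.001, 0.2),
    microform_spec("b", 0.3, 0.05, 100, 0.001, 0.2),
    microform_spec("c", 0.5, 0.05, 100, 0.001, 0.2)))
  d3 <- data.frame(date = as.Date("2021-06-01"),
                   microform = c("a", "b", "c"),
                   gpp = 0, reco = c(10, 10, 10), nee = 10)
  p3 <- partition_day(d3, sc3, 0, 0, 1)     # weights 2:3:5 via areal shares
  expect_equal(p3$reco, c(0.2, 0.3, 0.5))
  # zero-weight fallback to areal shares, flagged
  dz <- day(c(0, 0), c(0, 0))
  pz <- partition_day(dz, sc, 0, -1, 0.5)
  expect_true(all(pz$fallback))
  expect_equal(pz$reco, c(0.4, 0.6) * 0.5)
  expect_error(partition_day(day(c(0, 0), c(-1, 1)), sc, 0, 0, 1),
               "negative Reco weight")
})

test_that("partitioning conserves EC totals on random days", {
  sc <- toy_scenario()
  set.seed(99)
  for (i in 1:25) {
    d <- data.frame(date = as.Date("2021-06-01") + i,
                    microform = c("hollow", "hummock"),
                    gpp = -runif(2, 0, 5), reco = runif(2, 0, 5))
    d$nee <- d$gpp + d$reco
    ec_gpp <- -runif(1, 0, 8); ec_reco <- runif(1, 0, 8)
    p <- partition_day(d, sc, 0, ec_gpp, ec_reco)
    expect_lt(abs(sum(p$gpp) - ec_gpp), 1e-12)
    expect_lt(abs(sum(p$reco) - ec_reco), 1e-12)
    expect_lt(abs(sum(p$nee) - (ec_gpp + ec_reco)), 1e-12)
    expect_true(all(p$reco >= 0) && all(p$gpp <= 0))
    expect_equal(sum(p$rel_gpp), 1)
    expect_equal(sum(p$rel_reco), 1)
  }
})

test_that("annual_sums reproduces published share arithmetic", {
  # published open-site rows: Reco {296.8, 521.1} -> shares {36.3, 63.7}
  expect_equal(round(contribution_shares(c(296.8, 521.1)), 1), c(36.3, 63.7))
  # GPP {-464.8, -615.4} -> shares {43, 57}
  expect_equal(round(contribution_shares(c(-464.8, -615.4))), c(43, 57))
  expect_equal(contribution_shares(5), 100)
  expect_equal(contribution_shares(c(0, 0)), c(0, 0))

  # full-year bookkeeping and the missing-day error
  days <- seq(as.Date("2020-11-01"), by = 1, length.out = 365)
  part <- data.frame(date = rep(days, each = 2),
                     microform = c("hollow", "hummock"),
                     rel_gpp = 0.5, rel_reco = 0.5,
                     gpp = c(-1, -2), reco = c(1, 3), nee = c(0, 1),
                     fallback = FALSE)
  ann <- annual_sums(part, as.Date("2020-11-01"))
  expect_equal(ann$reco, c(365, 3 * 365))
  expect_equal(ann$share_reco, c(25, 75))
  expect_equal(sum(ann$nee), 365)
  expect_error(annual_sums(part[part$date != days[100], ],
                           as.Date("2020-11-01")), "missing day")
})
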