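test_that("depth integration conserves mass with correct units", {
  hyps <- cylinder_hyps(total = 3.234e9)
  # uniform 1 ug/L over the whole column: mass = c * V
  out <- depth_integrated_mass(rep(1, 121), 0:120, hyps)
  expect_equal(out$total_tons, 3.234, tolerance = 1e-12)
  expect_equal(sum(out$strata$mass_tons), out$total_tons)
  expect_equal(sum(out$strata$fraction), 1)

  zero <- depth_integrated_mass(rep(0, 121), 0:120, hyps)
  expect_equal(zero$total_tons, 0)
  expect_true(all(zero$strata$mass_tons == 0))

  # 10 ug/L confined to one 1-m layer of 5e7 m^3
  hyps2 <- cylinder_hyps(total = 120 * 5e7)
  conc <- rep(0, 121); conc[36] <- 10   # cell with top depth 35 m
  single <- depth_integrated_mass(conc, 0:120, hyps2)
  expect_equal(single$total_tons, 0.5)
  expect_equal(single$strata$mass_tons[single$strata$stratum_top == 20], 0.5)
  expect_true(all(single$strata$mass_tons[single$strata$stratum_top != 20] == 0))

  expect_error(depth_integrated_mass(rep(1, 50), 0:49, hyps), "grid")
})

test_that("mass conservation holds for random profiles with missing cells", {
  set.seed(5)
  hyps <- make_hypsography()
  for (i in 1:25) {
    conc <- runif(121, 0, 30)
    conc[sample(121, 10)] <- NA
    out <- depth_integrated_mass(conc, 0:120, hyps)
    expect_equal(sum(out$strata$mass_tons), out$total_tons,
                 tolerance = 1e-9)
    expect_equal(out$n_missing, sum(is.na(conc[1:120])))
  }
})

test_that("net growth rate is the log ratio per day and telescopes", {
  d0 <- as.Date("2020-06-01")
  expect_equal(net_growth_rate(5, 5, d0, d0 + 10), 0)
  expect_equal(net_growth_rate(1, 2, d0, d0 + 14), log(2) / 14)
  expect_equal(net_growth_rate(2, 1, d0, d0 + 14),
               -net_growth_rate(1, 2, d0, d0 + 14))
  expect_error(net_growth_rate(0, 1, d0, d0 + 1),
               class = "limnobloom_undefined_growth")
  expect_error(net_growth_rate(1, 1, d0, d0), "later")

  # telescoping: summed interval growth equals the endpoint log ratio
  set.seed(8)
  b <- exp(cumsum(rnorm(20, 0, 0.3))) * 10
  dates <- d0 + cumsum(sample(7:21, 20, replace = TRUE))
  mus <- net_growth_rate(b[-20], b[-1], dates[-20], dates[-1])
  days <- as.numeric(diff(dates))
  expect_equal(sum(mus * days), log(b[20]) - log(b[1]), tolerance = 1e-10)
})

test_that("chlorophyll maximum depth uses the shallow tie-break", {
  gauss <- exp(-((0:40) - 11)^2 / 8)
  expect_equal(chl_max_depth(gauss, 0:40)$z_plankt, 11)

  bimodal <- rep(0, 21); bimodal[6] <- 2; bimodal[13] <- 2
  expect_equal(chl_max_depth(bimodal, 0:20)$z_plankt, 5)

  faint <- chl_max_depth(rep(0.01, 50), 0:49)
  expect_true(faint$below_detection)

  empty <- chl_max_depth(rep(0, 10), 0:9)
  expect_true(is.na(empty$z_plankt))
  expect_true(empty$below_detection)
})

test_that("regime labels follow metalimnion validity and position", {
  expect_equal(regime_label(12, TRUE, 8), "metalimnetic")
  expect_equal(regime_label(12, FALSE, NA), "mixed")
  expect_equal(regime_label(3, TRUE, 8), "mixed")
  expect_true(is.na(regime_label(NA, TRUE, 8)))
  expect_equal(regime_label(c(12, 3), c(TRUE, TRUE), c(8, 8)),
               c("metalimnetic", "mixed"))
})

test_that("annual extremes yield the constructed survival/recovery ratios", {
  # year 1: spring min 1, following max 20; year 2: spring min 2
  dates <- c(as.Date("2009-05-10"), as.Date("2009-12-10"),
             as.Date("2010-05-10"), as.Date("2010-11-10"))
  pop <- tibble::tibble(timestamp = dates, total_tons = c(1, 20, 2, 15))
  ex <- annual_extremes(pop)
  expect_equal(ex$vernal_min, c(1, 2))
  expect_equal(ex$following_max, c(20, 15))
  expect_equal(ex$recovery_ratio[1], 1 / 20)
  expect_equal(ex$survival_ratio[2], 2 / 20)
  expect_true(is.na(ex$survival_ratio[1]))
  expect_false(any(ex$min_below_detection))

  # flat series: min = max, both ratios 1
  flat <- tibble::tibble(
    timestamp = seq(as.Date("2009-01-15"), as.Date("2011-12-15"), by = "month"),
    total_tons = 7
  )
  exf <- annual_extremes(flat)
  expect_true(all(exf$recovery_ratio == 1))
  expect_true(all(exf$survival_ratio[-1] == 1))

  # a below-detection minimum is floored and flagged
  low <- pop; low$total_tons[3] <- 0.001
  exl <- annual_extremes(low)
  expect_true(exl$min_below_detection[2])
  expect_equal(exl$survival_ratio[2], 0.05 / 20)  # floored at 0.05 t
})

test_that("congruence deviations follow the sign convention", {
  pop <- tibble::tibble(timestamp = as.Date("2020-07-01") + 0:2,
                        z_plankt = c(10, 12, 8), total_tons = 1,
                        below_detection = FALSE)
  light <- tibble::tibble(timestamp = pop$timestamp,
                          z_buoy = c(10, NA, 9), z_eu = c(11, 10, NA))
  strat <- tibble::tibble(timestamp = pop$timestamp,
                          metalimnion_lower = c(12, 13, 14),
                          metalimnion_valid = c(TRUE, TRUE, TRUE))
  out <- congruence_series(pop, light, strat)
  expect_equal(out$dev_z_buoy, c(0, NA, 1))
  expect_equal(out$dev_z_eu, c(1, -2, NA))
  expect_equal(out$dev_meta_lower, c(2, 1, 6))
})

test_that("growth series flags floored intervals and labels regimes at t0", {
  dates <- as.Date("2020-06-01") + c(0, 14, 28)
  pop <- structure(
    tibble::tibble(timestamp = dates, total_tons = c(0.01, 1, 2),
                   z_plankt = c(12, 12, 3), below_detection = c(TRUE, FALSE, FALSE),
                   n_missing_cells = 0, strata = list(NULL, NULL, NULL)),
    class = c("population_series", class(tibble::tibble()))
  )
  strat <- tibble::tibble(timestamp = dates,
                          metalimnion_valid = c(TRUE, TRUE, TRUE),
                          metalimnion_upper = c(8, 8, 8))
  g <- growth_series(pop, strat)
  expect_equal(nrow(g), 2)
  expect_true(g$floored[1])
  expect_false(g$floored[2])
  expect_equal(g$regime, c("metalimnetic", "metalimnetic"))
  # first interval uses the floored 0.05 t start mass
  expect_equal(g$mu[1], (log(1) - log(0.05)) / 14)
})
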