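test_that("turbulent fluxes vanish when both gradients vanish", {
  for (w in c(0, 3, 8)) {
    # saturated air at the surface temperature: no vapour or heat gradient
    out <- bulk_turbulent_fluxes(15, 100, 980, w, 15)
    expect_equal(out$q_latent, 0, tolerance = 1e-9)
    expect_equal(out$q_sensible, 0, tolerance = 1e-9)
    expect_true(out$converged)
  }
})

test_that("turbulent fluxes grow with wind under fixed gradients", {
  calm <- bulk_turbulent_fluxes(10, 70, 980, 0, 15)
  windy <- bulk_turbulent_fluxes(10, 70, 980, 5, 15)
  expect_lt(abs(calm$q_latent), abs(windy$q_latent))
  expect_lt(abs(calm$q_sensible), abs(windy$q_sensible))
  # warm lake under cooler air loses heat in both channels
  expect_lt(windy$q_latent, 0)
  expect_lt(windy$q_sensible, 0)
})

test_that("bulk fluxes match an independent scalar implementation", {
  # plain-loop reimplementation of the same bulk formulas, kept separate
  # from the package code path
  ref_fluxes <- function(ta, rh, p, u, ts) {
    esat <- function(t) 6.112 * exp(17.62 * t / (243.12 + t))
    shum <- function(e, p) 0.622 * e / (p - 0.378 * e)
    ea <- rh / 100 * esat(ta); qa <- shum(ea, p); qs <- shum(esat(ts), p)
    tak <- ta + 273.15
    tv <- tak * (1 + 0.608 * qa)
    rho <- 100 * p / (287.05 * tv)
    lv <- 2.501e6 - 2370 * ts
    cd <- 1.3e-3; ch <- 1.35e-3; ce <- 1.35e-3
    for (i in 1:50) {
      h <- rho * 1005 * ch * u * (ta - ts)
      e <- rho * lv * ce * u * (qa - qs)
      us <- sqrt(cd) * u
      wtv <- h / (rho * 1005) + 0.61 * tak * e / (rho * lv)
      if (abs(wtv) < 1e-12) break
      L <- -us^3 * tv / (0.4 * 9.81 * wtv)
      z <- max(min(10 / L, 10), -10)
      if (z < 0) {
        x <- (1 - 16 * z)^0.25
        pm <- 2 * log((1 + x) / 2) + log((1 + x^2) / 2) - 2 * atan(x) + pi / 2
        ph <- 2 * log((1 + x^2) / 2)
      } else {
        pm <- -5 * z; ph <- -5 * z
      }
      dm <- max(1 - sqrt(1.3e-3) / 0.4 * pm, 0.1)
      dh <- max(1 - 1.35e-3 / (0.4 * sqrt(1.3e-3)) * ph, 0.1)
      cdn <- 1.3e-3 / dm^2
      chn <- 1.35e-3 / (dm * dh)
      cen <- 1.35e-3 / (dm * dh)
      if (max(abs(cdn - cd) / cd, abs(chn - ch) / ch) < 1e-4) {
        cd <- cdn; ch <- chn; ce <- cen
        break
      }
      cd <- cdn; ch <- chn; ce <- cen
    }
    c(latent = rho * lv * ce * u * (qa - qs),
      sensible = rho * 1005 * ch * u * (ta - ts))
  }
  got <- bulk_turbulent_fluxes(10, 70, 980, 3, 15)
  want <- ref_fluxes(10, 70, 980, 3, 15)
  expect_lt(abs(got$q_latent - want["latent"]), 0.5)
  expect_lt(abs(got$q_sensible - want["sensible"]), 0.5)
})

test_that("radiative fluxes are linear in the calibration constant", {
  met <- tibble::tibble(date = as.Date("2020-06-21"), tair_c = 18,
                        rh_pct = 65, swdown_wm2 = 250, tsurf_c = 20)
  r1 <- radiative_fluxes(met, a = 1)
  r2 <- radiative_fluxes(met, a = 2)
  expect_equal(r2$q_lw_in, 2 * r1$q_lw_in)
  expect_equal(r2$q_sw_net, r1$q_sw_net)
  expect_equal(r1$q_sw_net, (1 - 0.07) * 250)

  dark <- radiative_fluxes(dplyr::mutate(met, swdown_wm2 = 0), a = 1)
  expect_equal(dark$q_sw_net, 0)
  expect_error(radiative_fluxes(met, a = -1), "positive")
})

test_that("longwave balance closes for a blackbody atmosphere at equal temperature", {
  met <- tibble::tibble(date = as.Date("2020-06-21"), tair_c = 15,
                        rh_pct = 70, swdown_wm2 = 200, tsurf_c = 15)
  cfg <- pipeline_config(emissivity_water = 1)
  sw_clear <- clear_sky_radiation(met$date, cfg$latitude_deg, cfg$transmissivity)
  cloud <- min(max(1 - met$swdown_wm2 / sw_clear, 0), 1)
  e_a <- met$rh_pct / 100 * saturation_vapor_pressure(met$tair_c)
  eps <- atmospheric_emissivity(met$tair_c, e_a, cloud)
  r <- radiative_fluxes(met, a = 1 / eps, config = cfg)
  expect_equal(r$q_lw_in - r$q_lw_out, 0, tolerance = 1e-9)
})

test_that("heat content integrates density times heat capacity over layers", {
  hyps <- cylinder_hyps(total = 1.2e9)
  t1 <- rep(5, 121)
  t2 <- rep(6, 121)
  dh <- heat_content(t2, 0:120, hyps) - heat_content(t1, 0:120, hyps)
  expect_equal(dh / (1000 * 4186 * 1.2e9), 1, tolerance = 1e-3)
  expect_identical(heat_content(rep(0, 121), 0:120, hyps), 0)

  # two-layer profile against a per-cell brute-force summation
  temp <- c(rep(15, 20), rep(5, 101))
  brute <- sum(water_density(pmax(temp[1:120], 0.01), 0) * 4186 *
                 temp[1:120] * hyps$volume_m3)
  expect_equal(heat_content(temp, 0:120, hyps), brute)
})

test_that("the longwave constant is recovered from a closed budget", {
  for (a_true in c(0.9, 1.0, 1.1)) {
    sim <- simulate_heat_budget(n_years = 2, a_true = a_true, seed = 3)
    fit <- fit_longwave_constant(sim$met, sim$heat_series, sim$lake_area)
    expect_equal(fit$a, a_true, tolerance = 1e-6)
  }
  # monotone in the generator's constant
  fits <- vapply(c(0.9, 1.0, 1.1), function(a) {
    sim <- simulate_heat_budget(n_years = 2, a_true = a, seed = 3,
                                heat_noise_cv = 0.02)
    fit_longwave_constant(sim$met, sim$heat_series, sim$lake_area)$a
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("sign conventions hold in synthetic midsummer and winter records", {
  sim <- simulate_heat_budget(n_years = 1, a_true = 1.02, seed = 5)
  flux <- surface_fluxes(sim$met, a = 1.02)
  doy <- as.numeric(format(flux$date, "%j"))
  expect_true(all(flux$q_sw_net[doy > 150 & doy < 230] > 0))
  # clear cold winter days: strong net heat loss
  winter_clear <- doy < 45 & sim$met$swdown_wm2 > 0.7 *
    clear_sky_radiation(sim$met$date) & sim$met$tair_c < 2
  if (any(winter_clear)) expect_true(mean(flux$q_net[winter_clear]) < 0)
})

test_that("seasonal climatology centres anomalies and flags outliers", {
  days <- seq(as.Date("2009-01-01"), as.Date("2020-12-31"), by = "day")
  const <- tibble::tibble(date = days, value = 3)
  clim <- seasonal_climatology(const)
  expect_true(all(clim$anomaly == 0))
  expect_false(any(clim$flagged))

  # December belongs to the following year's winter
  expect_equal(clim$year[clim$season == "DJF"][1], 2009)
  dec <- tibble::tibble(date = as.Date("2010-12-15"), value = 1)
  expect_equal(seasonal_climatology(
    dplyr::bind_rows(const, dec))$year[1], 2009)

  # one winter shifted far out is the only flagged winter
  set.seed(2)
  vals <- rnorm(length(days), 10, 1)
  shift <- lubridate::year(days) == 2015 &
    lubridate::month(days) %in% c(12, 1, 2)
  shifted <- vals + ifelse(lubridate::month(days) %in% c(1, 2) &
                             lubridate::year(days) == 2015, 25, 0)
  clim2 <- seasonal_climatology(tibble::tibble(date = days, value = shifted))
  djf <- clim2[clim2$season == "DJF", ]
  expect_true(djf$flagged[djf$year == 2015])
  expect_equal(sum(djf$flagged), 1)
  # anomalies of each season sum to zero
  sums <- tapply(clim2$anomaly, clim2$season, sum)
  expect_equal(unname(as.numeric(sums)), rep(0, 4), tolerance = 1e-9)
})
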