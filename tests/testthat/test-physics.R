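test_that("salinity conversion is the lake-specific linear factor", {
  expect_equal(salinity_from_conductivity(0), 0)
  expect_equal(salinity_from_conductivity(200), 0.15998)
  expect_equal(salinity_from_conductivity(1), 7.999e-4)
  expect_equal(salinity_from_conductivity(c(0, 100, 200)),
               c(0, 0.07999, 0.15998))
  expect_error(salinity_from_conductivity(-1), "non-negative")
})

test_that("potential temperature is a small surface-referenced correction", {
  expect_identical(potential_temperature(10, 0), 10)
  th <- potential_temperature(5, 120)
  expect_gte(th, 4.98)
  expect_lte(th, 5.00)
  # correction grows with depth, cooling for water above maximum density
  ths <- potential_temperature(rep(10, 4), c(0, 40, 80, 140))
  expect_true(all(diff(ths) < 0))
  # bounded below 0.02 K over the whole monitored depth range
  for (t in c(4, 5, 7, 10)) {
    expect_lt(abs(potential_temperature(t, 140) - t), 0.02)
  }
})

test_that("pure-water density peaks near 4 degC and rejects bad input", {
  r4 <- potential_density(4)
  expect_gte(r4, 999.970)
  expect_lte(r4, 999.975)
  expect_lt(potential_density(3), r4)
  expect_lt(potential_density(5), r4)
  expect_lt(potential_density(25), potential_density(10))
  expect_error(potential_density(-1), "range")
  expect_error(potential_density(40), "range")
})

test_that("haline correction is exactly multiplicative", {
  expect_identical(water_density(4, 0), potential_density(4))
  expect_equal(water_density(4, 0.2),
               potential_density(4) * (1 + 0.807e-3 * 0.2))
  # rho / rho_theta - 1 = beta * S as an algebraic identity
  set.seed(1)
  theta <- runif(50, 1, 30)
  sal <- runif(50, 0, 0.5)
  expect_equal(water_density(theta, sal) / potential_density(theta) - 1,
               0.807e-3 * sal, tolerance = 1e-12)
  # strictly increasing in salinity
  expect_true(all(diff(water_density(rep(10, 5), seq(0, 0.4, 0.1))) > 0))
  expect_error(water_density(4, -0.1), "non-negative")
})

test_that("buoyancy frequency matches the closed form on linear profiles", {
  rho <- 1000 + 0.01 * (0:120)
  n2 <- buoyancy_frequency(rho)
  expect_lt(max(abs(n2[2:120] - 9.81 * 0.01 / rho[2:120])), 1e-8)
  expect_equal(buoyancy_frequency(rep(1000, 50)), rep(0, 50))
  expect_true(all(buoyancy_frequency(1000 - 0.01 * (0:30)) < 0))
  expect_error(buoyancy_frequency(1000), "at least 2")
})

test_that("mixed-layer depth uses strict exceedance over the top-2-m mean", {
  rho <- c(rep(999.90, 13), rep(1000.10, 108))  # step between 12 and 13 m
  out <- mixed_layer_depth(rho, 0:120)
  expect_equal(out$z_mix, 13)
  expect_false(out$full_mixing)

  unif <- mixed_layer_depth(rep(1000, 121), 0:120)
  expect_equal(unif$z_mix, 120)
  expect_true(unif$full_mixing)

  # an increase of exactly the offset does not trigger the criterion
  rho2 <- c(rep(1000, 20), rep(1000.01, 101))
  expect_true(mixed_layer_depth(rho2, 0:120)$full_mixing)

  expect_error(mixed_layer_depth(c(1000, 1000.2), c(5, 6)), "surface")
})

test_that("mixed-layer depth matches a brute-force scan on random steps", {
  set.seed(42)
  depth <- 0:120
  for (i in 1:100) {
    zstep <- sample(3:110, 1)
    jump <- runif(1, 0.001, 0.3)
    rho <- 999.9 + ifelse(depth >= zstep, jump, 0) + 1e-4 * depth
    got <- mixed_layer_depth(rho, depth)$z_mix
    ref <- mean(rho[depth <= 2])
    hit <- which(rho > ref + 0.01)
    want <- if (length(hit)) depth[hit[1]] else 120
    expect_identical(got, want)
    # monotone response: deepening the step cannot shoal z_mix
    rho_deeper <- 999.9 + ifelse(depth >= zstep + 5, jump, 0) + 1e-4 * depth
    expect_gte(mixed_layer_depth(rho_deeper, depth)$z_mix, got)
  }
})

test_that("metalimnion detection interpolates half-max crossings", {
  # triangle: 0 at 5 m, 4e-4 at 10 m, 0 at 15 m
  n2 <- approx(c(0, 5, 10, 15, 30), c(0, 0, 4e-4, 0, 0), xout = 0:30)$y
  out <- detect_metalimnion(n2, 0:30)
  expect_equal(out$metalimnion_center, 10)
  expect_equal(out$metalimnion_upper, 7.5)
  expect_equal(out$metalimnion_lower, 12.5)
  expect_true(out$metalimnion_valid)

  # flat profile: no crossing, clipped to the grid, too thick to be valid
  flat <- detect_metalimnion(rep(3e-4, 121), 0:120)
  expect_equal(flat$metalimnion_upper, 0)
  expect_equal(flat$metalimnion_lower, 120)
  expect_false(flat$metalimnion_valid)

  # below the stability threshold the shape does not matter
  weak <- detect_metalimnion(approx(c(0, 10, 20), c(0, 1e-4, 0), xout = 0:20)$y,
                             0:20)
  expect_false(weak$metalimnion_valid)

  # fully unstable column: no boundaries at all
  unstable <- detect_metalimnion(rep(-1e-4, 50))
  expect_false(unstable$metalimnion_valid)
  expect_true(is.na(unstable$metalimnion_upper))
})

test_that("metalimnion thickness is scale-invariant but validity is not", {
  set.seed(7)
  for (i in 1:50) {
    center <- sample(8:60, 1)
    width <- sample(3:8, 1)
    n2 <- 5e-4 * exp(-((0:120) - center)^2 / (2 * width^2))
    a <- detect_metalimnion(n2, 0:120)
    b <- detect_metalimnion(10 * n2, 0:120)
    expect_equal(b$metalimnion_lower - b$metalimnion_upper,
                 a$metalimnion_lower - a$metalimnion_upper, tolerance = 1e-9)
    expect_equal(a$metalimnion_center, b$metalimnion_center)
    # boundaries bracket the argmax
    expect_lte(a$metalimnion_upper, a$metalimnion_center)
    expect_gte(a$metalimnion_lower, a$metalimnion_center)
    # scaling down below the threshold kills validity, not geometry
    c_ <- detect_metalimnion(n2 / 5, 0:120)
    expect_false(c_$metalimnion_valid)
  }
})

test_that("stratification summaries recover a constructed two-layer lake", {
  depth <- 0:120
  temp <- ifelse(depth <= 10, 15, 5 + 10 * exp(-(depth - 10) / 3))
  cond <- rep(210, 121)
  profiles <- tibble::tibble(
    timestamp = as.Date("2020-07-15"), depth_m = depth,
    temp_c = temp, cond25_uScm = cond
  )
  out <- stratify_profiles(profiles)
  expect_s3_class(out, "strat_summary")
  expect_equal(nrow(out), 1)
  expect_true(out$metalimnion_valid)
  expect_equal(out$z_mix, 11)
  expect_true(out$metalimnion_center >= 10 && out$metalimnion_center <= 14)
})
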