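test_that("saturation vapor pressure follows the Tetens curve", {
  expect_equal(saturation_vapor_pressure(0), 0.6108, tolerance = 1e-6)
  expect_equal(saturation_vapor_pressure(36), 5.9410, tolerance = 1e-4)
  # strictly increasing and continuous over the working range
  grid <- seq(-20, 60, by = 0.5)
  p <- saturation_vapor_pressure(grid)
  expect_true(all(p > 0))
  expect_true(all(diff(p) > 0))
  expect_lt(saturation_vapor_pressure(30), saturation_vapor_pressure(36))
  expect_error(saturation_vapor_pressure(75), "temperature")
})

test_that("convection coefficient follows the forced correlation with a floor", {
  expect_equal(convection_coefficient(2.5), 8.3 * 2.5^0.6)
  expect_equal(convection_coefficient(0.3), 8.3 * 0.3^0.6)
  expect_gt(convection_coefficient(0.3), 3.1)
  # near-still air hits the natural-convection floor
  expect_equal(convection_coefficient(0.01), 3.1)
  v <- seq(0.05, 10, by = 0.05)
  expect_true(all(diff(convection_coefficient(v)) >= 0))
  expect_error(convection_coefficient(0), "wind_speed")
})

test_that("clothing surface temperature solves the linear surface balance", {
  clothing <- clothing_parameters()
  config <- heat_balance_config()
  # no gradient, no solar: surface sits at skin temperature
  w <- weather_conditions(36, 0.5, 0, 2.5)
  expect_equal(clothing_surface_temperature(w, clothing, config), 36)
  # extreme-heat city day, no solar
  w <- weather_conditions(43.2, 0.16, 0, 2.5)
  expect_equal(clothing_surface_temperature(w, clothing, config), 40.12,
               tolerance = 1e-3)
  # zero insulation returns the skin-temperature limit, not a failure
  bare <- clothing_parameters(insulation = 0)
  w <- weather_conditions(43.2, 0.16, 600, 2.5)
  expect_equal(clothing_surface_temperature(w, bare, config), 36)
})

test_that("closed-form clothing temperature matches a numeric root-finder", {
  clothing <- clothing_parameters()
  config <- heat_balance_config()
  for (t_a in seq(10, 50, by = 5)) {
    for (v in c(0.3, 2.5)) {
      for (r_sol in c(0, 600)) {
        w <- weather_conditions(t_a, 0.5, r_sol, v)
        expect_equal(
          clothing_surface_temperature(w, clothing, config),
          clothing_temperature_uniroot(w, clothing, config),
          tolerance = 1e-6
        )
      }
    }
  }
})

test_that("solar gain is linear in flux and zero indoors", {
  clothing <- clothing_parameters()
  config <- heat_balance_config()
  indoors <- weather_conditions(30, 0.5, 0, 0.3)
  expect_equal(solar_gain(indoors, 1.81, clothing, config), 0)
  sunny <- weather_conditions(30, 0.5, 600, 2.5)
  expected <- 600 * 0.25 * 1.81 * (0.4 * 1.08 * 0.7 + 0.6 * 0.7)
  expect_equal(solar_gain(sunny, 1.81, clothing, config), expected)
  double <- weather_conditions(30, 0.5, 1200, 2.5)
  expect_equal(solar_gain(double, 1.81, clothing, config), 2 * expected)
  expect_error(solar_gain(sunny, 0, clothing, config), "surface_area")
})

test_that("dry heat exchange has the right zeros, signs, and monotonicity", {
  clothing <- clothing_parameters()
  config <- heat_balance_config()
  area <- 1.81
  neutral <- weather_conditions(36, 0.5, 0, 2.5)
  expect_equal(dry_heat_exchange(neutral, area, clothing, config), 0)
  # hotter air means less dry loss
  cool <- weather_conditions(25, 0.5, 0, 2.5)
  warm <- weather_conditions(35, 0.5, 0, 2.5)
  expect_gt(dry_heat_exchange(cool, area, clothing, config),
            dry_heat_exchange(warm, area, clothing, config))
  # above skin temperature the body gains heat through the dry pathway
  extreme <- weather_conditions(43.2, 0.16, 0, 2.5)
  expect_lt(dry_heat_exchange(extreme, area, clothing, config), 0)
})

test_that("evaporative loss is the smaller of sweat and environment limits", {
  clothing <- clothing_parameters()
  config <- heat_balance_config()
  area <- 1.81
  # saturated air at skin temperature: no vapor-pressure gradient
  saturated <- weather_conditions(36, 1.0, 0, 2.5)
  e <- evaporative_heat_loss(saturated, area, 9.41, clothing, config)
  expect_equal(e$capacity, 0)
  expect_equal(e$loss, 0)
  # dry heat: loss is sweat-limited at the classic textbook value
  dry <- weather_conditions(43.2, 0.16, 0, 2.5)
  e <- evaporative_heat_loss(dry, area, 9.41, clothing, config)
  expect_equal(e$loss, 9.41 * 1.81 * 2426 * 0.85 / 60, tolerance = 1e-9)
  expect_lt(e$loss, e$capacity)
  # loss never increases with humidity
  losses <- vapply(seq(0, 1, by = 0.1), function(phi) {
    w <- weather_conditions(38, phi, 0, 0.3)
    evaporative_heat_loss(w, area, 9.41, clothing, config)$loss
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("the heat budget closes exactly for random valid inputs", {
  n <- 10000
  w <- random_weather(n, seed = 7)
  set.seed(8)
  area <- stats::runif(n, 0.3, 2.6)
  sweat <- stats::runif(n, 0, 12)
  metab <- stats::runif(n, 80, 1500)
  clothing <- clothing_parameters()
  config <- heat_balance_config()
  parts <- heatstrain:::storage_components(w, area, sweat, metab,
                                           clothing, config)
  # recompute each component through the public operations
  residual <- metab +
    solar_gain(w, area, clothing, config) -
    dry_heat_exchange(w, area, clothing, config) -
    evaporative_heat_loss(w, area, sweat, clothing, config)$loss -
    parts$storage
  expect_lt(max(abs(residual)), 1e-9)
  expect_true(all(parts$evaporative_loss >= 0))
  expect_true(all(parts$evaporative_loss <= parts$evaporative_capacity + 1e-12))
})

test_that("storage is monotone in each weather driver and in physiology", {
  clothing <- clothing_parameters()
  config <- heat_balance_config()
  storage_at <- function(t_a, phi, r_sol, sweat = 5, metab = 400) {
    w <- weather_conditions(t_a, phi, r_sol, 2.5)
    heatstrain:::storage_components(w, 1.81, sweat, metab, clothing,
                                    config)$storage
  }
  temps <- seq(15, 48, length.out = 12)
  expect_true(all(diff(vapply(temps, storage_at, numeric(1),
                              phi = 0.4, r_sol = 300)) >= 0))
  phis <- seq(0, 1, length.out = 11)
  expect_true(all(diff(vapply(phis, function(p)
    storage_at(38, p, 300), numeric(1))) >= 0))
  sols <- seq(0, 1000, length.out = 11)
  expect_true(all(diff(vapply(sols, function(r)
    storage_at(38, 0.4, r), numeric(1))) >= 0))
  metabs <- seq(100, 1400, length.out = 11)
  expect_true(all(diff(vapply(metabs, function(m)
    storage_at(38, 0.4, 300, metab = m), numeric(1))) >= 0))
  # more sweat never increases storage while sweat-limited
  sweats <- seq(0, 8, length.out = 9)
  expect_true(all(diff(vapply(sweats, function(s)
    storage_at(43, 0.2, 300, sweat = s), numeric(1))) <= 0))
})

test_that("limiting cases of the budget behave as energy reasoning demands", {
  clothing <- clothing_parameters()
  config <- heat_balance_config()
  # at air = skin temperature with no sun, storage is metabolic minus sweat
  w <- weather_conditions(36, 0.3, 0, 2.5)
  parts <- heatstrain:::storage_components(w, 1.81, 6, 400, clothing, config)
  expect_equal(parts$storage, 400 - parts$evaporative_loss)
  # a sweat-limited female stores at least as much as her male counterpart
  melbourne <- weather_conditions(43.2, 0.16, 600, 2.5)
  for (age in c(20, 40, 80)) {
    female <- heat_storage(melbourne,
                           build_body_profile(age, "female", 70, 170,
                                              "moderate"))
    male <- heat_storage(melbourne,
                         build_body_profile(age, "male", 70, 170,
                                            "moderate"))
    expect_lt(female$evaporative_loss, female$evaporative_capacity)
    expect_gte(female$storage, male$storage)
  }
})

test_that("hourly temperature gain inverts the storage threshold", {
  expect_equal(hourly_temperature_gain(0, 70), 0)
  # the storage that produces exactly the 2 degC/h threshold
  storage_for <- function(gain, mass) gain * 3.5 * mass * 1000 / 3600
  for (mass in c(10, 35, 70, 105, 140)) {
    expect_equal(hourly_temperature_gain(storage_for(2, mass), mass), 2)
  }
  expect_equal(storage_for(2, 70), 136.1, tolerance = 1e-3)
  # inverse proportionality to mass
  expect_equal(hourly_temperature_gain(200, 140),
               hourly_temperature_gain(200, 70) / 2)
  expect_error(hourly_temperature_gain(100, 0), "mass")
})

test_that("risk classification is inclusive and configurable", {
  expect_true(is_at_risk(2.0))
  expect_false(is_at_risk(1.999))
  expect_true(is_at_risk(1.7, heat_balance_config(risk_threshold = 1.5)))
})

test_that("respiratory loss flag reduces the metabolic term when enabled", {
  w <- weather_conditions(30, 0.5, 0, 2.5)
  on <- heat_balance_config(include_respiratory_loss = TRUE)
  off <- heat_balance_config()
  with_flag <- heatstrain:::storage_components(w, 1.81, 6, 400,
                                               clothing_parameters(), on)
  without <- heatstrain:::storage_components(w, 1.81, 6, 400,
                                             clothing_parameters(), off)
  expect_lt(with_flag$metabolic, without$metabolic)
  expect_equal(without$metabolic, 400)
})

test_that("weather conditions validate their physical ranges", {
  expect_error(weather_conditions(70, 0.5, 0, 1), "air_temperature")
  expect_error(weather_conditions(30, 1.5, 0, 1), "relative_humidity")
  expect_error(weather_conditions(30, 0.5, -1, 1), "solar_radiation")
  expect_error(weather_conditions(30, 0.5, 0, 0), "wind_speed")
})
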