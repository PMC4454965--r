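#' Weather conditions experienced by an individual
#'
#' One station-time observation expressed at the individual level: air
#' temperature, relative humidity (as a fraction), global solar radiation
#' on the horizontal (zero indoors), and the effective wind speed at the
#' body (2.5 m.s^-1 outdoors for a light breeze, 0.3 m.s^-1 indoors for
#' body movement; see [to_exposure_weather()]).
#'
#' @param air_temperature Air temperature, degrees C, in `[-20, 60]`.
#' @param relative_humidity Relative humidity as a fraction in `[0, 1]`.
#' @param solar_radiation Global solar radiation, W.m^-2, non-negative.
#' @param wind_speed Effective wind speed at the body, m.s^-1, positive.
#'
#' @return An object of class `weather_conditions`.
#' @export
#' @examples
#' weather_conditions(43.2, 0.16, 600, 2.5)
weather_conditions <- function(air_temperature, relative_humidity,
                               solar_radiation, wind_speed) {
  if (any(air_temperature < -20 | air_temperature > 60)) {
    stop("air_temperature must lie in [-20, 60] degrees C", call. = FALSE)
  }
  if (any(relative_humidity < 0 | relative_humidity > 1)) {
    stop("relative_humidity must be a fraction in [0, 1]", call. = FALSE)
  }
  if (any(solar_radiation < 0)) {
    stop("solar_radiation must be non-negative", call. = FALSE)
  }
  if (any(wind_speed <= 0)) {
    stop("wind_speed must be positive", call. = FALSE)
  }
  structure(
    list(
      air_temperature = air_temperature,
      relative_humidity = relative_humidity,
      solar_radiation = solar_radiation,
      wind_speed = wind_speed
    ),
    class = "weather_conditions"
  )
}

#' Saturation vapor pressure of water (Tetens form)
#'
#' `p = 0.6108 * exp(17.27 * T / (T + 237.3))` kPa, valid over the model's
#' working range of -20 to 60 degrees C.
#'
#' @param temperature Temperature in degrees C.
#' @return Saturation vapor pressure in kPa.
#' @export
#' @examples
#' saturation_vapor_pressure(0)   # ~0.611 kPa
#' saturation_vapor_pressure(36)  # ~5.94 kPa at skin temperature
saturation_vapor_pressure <- function(temperature) {
  if (any(temperature < -20 | temperature > 60)) {
    stop("temperature must lie in [-20, 60] degrees C", call. = FALSE)
  }
  0.6108 * exp(17.27 * temperature / (temperature + 237.3))
}

#' Convective heat-transfer coefficient
#'
#' Forced-convection correlation `h_c = 8.3 * v^0.6` with a
#' natural-convection floor (default 3.1 W.m^-2.K^-1) for near-still air.
#'
#' @param wind_speed Wind speed, m.s^-1, positive.
#' @param config A [heat_balance_config()].
#' @return Convective transfer coefficient, W.m^-2.K^-1.
#' @export
#' @examples
#' convection_coefficient(2.5) # outdoor light breeze, ~14.4
#' convection_coefficient(0.3) # indoor body movement, ~4.0
convection_coefficient <- function(wind_speed, config = heat_balance_config()) {
  if (any(wind_speed <= 0)) {
    stop("wind_speed must be positive", call. = FALSE)
  }
  pmax(8.3 * wind_speed^0.6, config$convection_coefficient_floor)
}

#' Clothing surface temperature
#'
#' Solves the steady-state energy balance of the clothing surface,
#' `(T_sk - T_cl) / I_cl = h_c * (T_cl - T_a) - (1 - albedo_cl) * f_p * R_sol`,
#' i.e. conduction through the garment equals convective loss minus
#' absorbed direct solar radiation. The balance is linear in `T_cl`, so the
#' solution is closed-form. As insulation tends to zero the surface
#' temperature tends to skin temperature; `insulation = 0` is returned as
#' that limit.
#'
#' @param weather A [weather_conditions()] object.
#' @param clothing A [clothing_parameters()] object.
#' @param config A [heat_balance_config()].
#' @return Clothing surface temperature, degrees C.
#' @export
clothing_surface_temperature <- function(weather,
                                         clothing = clothing_parameters(),
                                         config = heat_balance_config()) {
  h_c <- convection_coefficient(weather$wind_speed, config)
  t_sk <- clothing$skin_temperature
  if (clothing$insulation == 0) {
    return(rep_len(t_sk, max(length(weather$air_temperature), length(h_c))))
  }
  absorbed <- (1 - clothing$clothing_albedo) *
    config$projected_area_fraction * weather$solar_radiation
  (t_sk / clothing$insulation + h_c * weather$air_temperature + absorbed) /
    (h_c + 1 / clothing$insulation)
}

#' Solar heat gain
#'
#' Direct short-wave gain intercepted by the projected body area, split
#' between the clothed segment (area increased by the clothing area ratio,
#' reflecting with the clothing albedo) and bare skin:
#' `R_abs = R_sol * f_p * A * (p_cl * r_cl * (1 - albedo_cl) +
#' (1 - p_cl) * (1 - albedo_sk))`. Zero indoors.
#'
#' @param weather A [weather_conditions()] object.
#' @param surface_area Body surface area, m^2, positive.
#' @inheritParams clothing_surface_temperature
#' @return Absorbed solar power, W.
#' @export
solar_gain <- function(weather, surface_area,
                       clothing = clothing_parameters(),
                       config = heat_balance_config()) {
  if (any(surface_area <= 0)) {
    stop("surface_area must be positive", call. = FALSE)
  }
  absorptivity <-
    clothing$clothed_proportion * clothing$clothing_area_ratio *
      (1 - clothing$clothing_albedo) +
    (1 - clothing$clothed_proportion) * (1 - clothing$skin_albedo)
  weather$solar_radiation * config$projected_area_fraction * surface_area *
    absorptivity
}

#' Dry (sensible) heat exchange
#'
#' Sum of direct convection from bare skin,
#' `h_c * A * (1 - p_cl) * (T_sk - T_a)`, and conduction through the
#' clothing layer, `A * p_cl * (T_sk - T_cl) / I_cl`, with the clothing
#' surface temperature from [clothing_surface_temperature()]. Positive
#' values are net loss from the body; the sign flips as air temperature
#' crosses skin temperature (in the absence of solar load).
#'
#' @inheritParams solar_gain
#' @return Dry heat exchange, W (positive = loss).
#' @export
dry_heat_exchange <- function(weather, surface_area,
                              clothing = clothing_parameters(),
                              config = heat_balance_config()) {
  if (any(surface_area <= 0)) {
    stop("surface_area must be positive", call. = FALSE)
  }
  h_c <- convection_coefficient(weather$wind_speed, config)
  t_sk <- clothing$skin_temperature
  bare <- h_c * (1 - clothing$clothed_proportion) *
    (t_sk - weather$air_temperature)
  if (clothing$insulation == 0) {
    # zero-insulation limit: the garment flux equals the surface balance
    # evaluated at T_cl = T_sk
    per_area <- h_c * (t_sk - weather$air_temperature) -
      (1 - clothing$clothing_albedo) * config$projected_area_fraction *
        weather$solar_radiation
    clothed <- clothing$clothed_proportion * per_area
  } else {
    t_cl <- clothing_surface_temperature(weather, clothing, config)
    clothed <- clothing$clothed_proportion * (t_sk - t_cl) /
      clothing$insulation
  }
  surface_area * (bare + clothed)
}

#' Evaporative heat loss and environmental capacity
#'
#' Evaporation is the smaller of the sweat-limited loss
#' `E_sw = m_sw * A * lambda * eta / 60` (maximal sweat rate in
#' g.min^-1.m^-2, latent heat in J.g^-1, evaporation efficiency eta) and
#' the environmental capacity from the Lewis relation,
#' `E_max = lewis_ratio * h_c * A * (p_sat(T_sk) - phi * p_sat(T_a))`,
#' floored at zero when the air's vapor pressure exceeds that at the skin.
#'
#' @inheritParams solar_gain
#' @param max_sweat_rate Maximal sweat rate, g.min^-1.m^-2, non-negative.
#' @return A list with components `loss` (realized evaporative loss, W) and
#'   `capacity` (environmental evaporative capacity, W).
#' @export
#' @examples
#' w <- weather_conditions(43.2, 0.16, 0, 0.3)
#' evaporative_heat_loss(w, 1.81, 9.41)
evaporative_heat_loss <- function(weather, surface_area, max_sweat_rate,
                                  clothing = clothing_parameters(),
                                  config = heat_balance_config()) {
  if (any(max_sweat_rate < 0)) {
    stop("max_sweat_rate must be non-negative", call. = FALSE)
  }
  if (any(surface_area <= 0)) {
    stop("surface_area must be positive", call. = FALSE)
  }
  h_c <- convection_coefficient(weather$wind_speed, config)
  sweat_limited <- max_sweat_rate * surface_area *
    config$latent_heat_vaporization * clothing$evaporation_efficiency / 60
  gradient <- saturation_vapor_pressure(clothing$skin_temperature) -
    weather$relative_humidity * saturation_vapor_pressure(weather$air_temperature)
  capacity <- pmax(config$lewis_ratio * h_c * surface_area * gradient, 0)
  list(loss = pmin(sweat_limited, capacity), capacity = capacity)
}

# Standard respiratory heat loss (convective + evaporative components),
# W, given metabolic rate in W and ambient conditions. Used only when
# heat_balance_config(include_respiratory_loss = TRUE).
respiratory_heat_loss <- function(metabolic_rate, weather) {
  p_a <- weather$relative_humidity *
    saturation_vapor_pressure(weather$air_temperature)
  0.0014 * metabolic_rate * (34 - weather$air_temperature) +
    0.0173 * metabolic_rate * (5.87 - p_a)
}

# Vectorized flux components for a batch of individuals under one set of
# weather conditions. Internal workhorse behind heat_storage() and the
# population aggregation.
storage_components <- function(weather, surface_area, max_sweat_rate,
                               metabolic_rate,
                               clothing = clothing_parameters(),
                               config = heat_balance_config()) {
  metabolic <- metabolic_rate
  if (isTRUE(config$include_respiratory_loss)) {
    metabolic <- metabolic - respiratory_heat_loss(metabolic_rate, weather)
  }
  r_abs <- solar_gain(weather, surface_area, clothing, config)
  dry <- dry_heat_exchange(weather, surface_area, clothing, config)
  evap <- evaporative_heat_loss(weather, surface_area, max_sweat_rate,
                                clothing, config)
  list(
    metabolic = metabolic,
    solar_gain = r_abs,
    dry_exchange = dry,
    evaporative_loss = evap$loss,
    evaporative_capacity = evap$capacity,
    storage = metabolic + r_abs - dry - evap$loss
  )
}

#' Steady-state heat storage for one individual
#'
#' Central budget of the man model: storage is metabolic heat plus absorbed
#' solar radiation minus dry exchange minus evaporative loss,
#' `S = M + R_abs - C - E`. The returned breakdown carries every component
#' plus the implied hourly core-temperature gain.
#'
#' @param weather A [weather_conditions()] object.
#' @param body A [body_profile()] object.
#' @inheritParams clothing_surface_temperature
#' @return An object of class `flux_breakdown`: a list with fields
#'   `metabolic`, `solar_gain`, `dry_exchange`, `evaporative_loss`,
#'   `evaporative_capacity`, `storage` (all W) and `hourly_temp_gain`
#'   (degrees C per hour).
#' @export
#' @examples
#' b <- build_body_profile(age = 30, sex = "male", mass = 70, height = 170,
#'                         exertion = "moderate")
#' w <- weather_conditions(43.2, 0.16, 600, 2.5)
#' heat_storage(w, b)
heat_storage <- function(weather, body,
                         clothing = clothing_parameters(),
                         config = heat_balance_config()) {
  stopifnot(inherits(body, "body_profile"))
  parts <- storage_components(
    weather,
    surface_area = body$surface_area,
    max_sweat_rate = body$max_sweat_rate,
    metabolic_rate = body$metabolic_rate,
    clothing = clothing, config = config
  )
  parts$hourly_temp_gain <- hourly_temperature_gain(parts$storage, body$mass,
                                                    config)
  structure(parts, class = "flux_breakdown")
}

#' @export
print.flux_breakdown <- function(x, ...) {
  cat("Heat-balance breakdown (W):\n")
  cat(sprintf("  metabolic:        %8.1f\n", x$metabolic))
  cat(sprintf("  solar gain:       %8.1f\n", x$solar_gain))
  cat(sprintf("  dry exchange:     %8.1f  (positive = loss)\n",
              x$dry_exchange))
  cat(sprintf("  evaporative loss: %8.1f  (capacity %.1f)\n",
              x$evaporative_loss, x$evaporative_capacity))
  cat(sprintf("  storage:          %8.1f\n", x$storage))
  cat(sprintf("  hourly gain:      %8.2f degC/h\n", x$hourly_temp_gain))
  invisible(x)
}

#' Hourly core-temperature gain from heat storage
#'
#' Converts net heat storage (W) into the hourly rise in mean body
#' temperature using the specific heat capacity of body tissue:
#' `dT = S * 3600 / (c_b * mass * 1000)` with `c_b` in J.g^-1.K^-1.
#'
#' @param storage Net heat storage, W.
#' @param mass Body mass, kg, positive.
#' @param config A [heat_balance_config()].
#' @return Core-temperature gain, degrees C per hour.
#' @export
#' @examples
#' hourly_temperature_gain(136.11, 70) # ~2 degC/h, the risk threshold
hourly_temperature_gain <- function(storage, mass,
                                    config = heat_balance_config()) {
  if (any(mass <= 0)) {
    stop("mass must be positive", call. = FALSE)
  }
  storage * 3600 / (config$body_heat_capacity * mass * 1000)
}

#' Is an hourly temperature gain classed as at risk?
#'
#' Inclusive comparison against the configured risk threshold: a gain of
#' 2 degrees C or more in one hour (by default) marks the individual at
#' risk of heat stress.
#'
#' @param hourly_gain Hourly core-temperature gain, degrees C per hour.
#' @param config A [heat_balance_config()].
#' @return Logical.
#' @export
is_at_risk <- function(hourly_gain, config = heat_balance_config()) {
  hourly_gain >= config$risk_threshold
}
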