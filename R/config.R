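#' Clothing parameters for the heat-balance model
#'
#' Fixed clothing and skin properties used by the surface energy balance.
#' Defaults are the conventional single-layer summer-clothing values used
#' throughout the simulation: a 0.6 clo garment (0.6 x 0.155 =
#' 0.093 m^2.K.W^-1) covering 40% of the body, with identical skin and
#' clothing albedo of 0.3 and a fixed skin temperature of 36 degrees C.
#' Keeping skin temperature fixed (together with maximal sweating, see
#' [max_sweat_rate()]) avoids solving for an equilibrium skin temperature
#' and prevents evaporative heat loss from being overestimated.
#'
#' @param clothing_albedo Reflecting power of clothing (dimensionless).
#' @param clothed_proportion Proportion of the body surface covered by
#'   clothing, in `[0, 1]`.
#' @param clothing_area_ratio Factor increase in surface area for the
#'   clothed area (dimensionless).
#' @param evaporation_efficiency Proportion of secreted sweat that
#'   evaporates, in `[0, 1]`.
#' @param insulation Dry thermal insulation of clothing, m^2.K.W^-1.
#' @param skin_albedo Reflecting power of skin (dimensionless).
#' @param skin_temperature Fixed skin temperature, degrees C.
#'
#' @return An object of class `clothing_parameters`.
#' @export
#' @examples
#' clothing_parameters()
#' clothing_parameters(insulation = 0.155) # 1 clo
clothing_parameters <- function(clothing_albedo = 0.3,
                                clothed_proportion = 0.4,
                                clothing_area_ratio = 1.08,
                                evaporation_efficiency = 0.85,
                                insulation = 0.093,
                                skin_albedo = 0.3,
                                skin_temperature = 36) {
  stopifnot(
    clothing_albedo >= 0, clothing_albedo <= 1,
    clothed_proportion >= 0, clothed_proportion <= 1,
    clothing_area_ratio > 0,
    evaporation_efficiency >= 0, evaporation_efficiency <= 1,
    insulation >= 0,
    skin_albedo >= 0, skin_albedo <= 1
  )
  structure(
    list(
      clothing_albedo = clothing_albedo,
      clothed_proportion = clothed_proportion,
      clothing_area_ratio = clothing_area_ratio,
      evaporation_efficiency = evaporation_efficiency,
      insulation = insulation,
      skin_albedo = skin_albedo,
      skin_temperature = skin_temperature
    ),
    class = "clothing_parameters"
  )
}

#' Physical constants and switches of the heat-balance engine
#'
#' Bundles the numerical constants of the steady-state heat budget that are
#' not clothing properties: the specific heat capacity of body tissue
#' (3.5 J.g^-1.K^-1), the latent heat of vaporization of sweat at skin
#' temperature, the Lewis-relation coefficient linking convective and
#' evaporative transfer, the projected-area fraction intercepting direct
#' solar radiation, the natural-convection floor on the convective transfer
#' coefficient, and the risk threshold on hourly core-temperature gain
#' (2 degrees C per hour; individuals at or above it are classed at risk of
#' heat stress).
#'
#' @param body_heat_capacity Specific heat capacity of the body,
#'   J.g^-1.K^-1.
#' @param latent_heat_vaporization Latent heat of vaporization of sweat,
#'   J.g^-1.
#' @param lewis_ratio Evaporative capacity per unit convective transfer
#'   coefficient, W.m^-2.kPa^-1 per W.m^-2.K^-1.
#' @param projected_area_fraction Fraction of total body surface projected
#'   toward the solar beam, in `[0, 1]`.
#' @param convection_coefficient_floor Minimum (natural-convection)
#'   convective transfer coefficient, W.m^-2.K^-1.
#' @param include_respiratory_loss If `TRUE`, subtract a standard
#'   respiratory heat-loss term from the metabolic load.
#' @param risk_threshold Hourly core-temperature gain at or above which an
#'   individual is classed at risk, degrees C per hour.
#'
#' @return An object of class `heat_balance_config`.
#' @export
#' @examples
#' heat_balance_config()
#' heat_balance_config(risk_threshold = 1.5)
heat_balance_config <- function(body_heat_capacity = 3.5,
                                latent_heat_vaporization = 2426,
                                lewis_ratio = 16.5,
                                projected_area_fraction = 0.25,
                                convection_coefficient_floor = 3.1,
                                include_respiratory_loss = FALSE,
                                risk_threshold = 2.0) {
  stopifnot(
    body_heat_capacity > 0,
    latent_heat_vaporization > 0,
    lewis_ratio > 0,
    projected_area_fraction >= 0, projected_area_fraction <= 1,
    convection_coefficient_floor >= 0,
    is.logical(include_respiratory_loss),
    risk_threshold > 0
  )
  structure(
    list(
      body_heat_capacity = body_heat_capacity,
      latent_heat_vaporization = latent_heat_vaporization,
      lewis_ratio = lewis_ratio,
      projected_area_fraction = projected_area_fraction,
      convection_coefficient_floor = convection_coefficient_floor,
      include_respiratory_loss = include_respiratory_loss,
      risk_threshold = risk_threshold
    ),
    class = "heat_balance_config"
  )
}

#' Coefficients of the linear maximal-sweat-rate model
#'
#' Maximal sweat rate (g.min^-1.m^-2) is modelled as a linear function of
#' sex, acclimatization, and age in years:
#' `intercept + male_effect * male + acclimatization_effect * acclimatized +
#' age_slope * age`, with the male indicator forced to zero below
#' `child_age_cutoff` (pre-pubescent boys sweat like girls) and the result
#' clamped below at `floor` (the linear predictor goes negative for very old
#' unacclimatized females, which would be unphysiological).
#'
#' @param intercept Intercept, g.min^-1.m^-2.
#' @param male_effect Additional sweat rate for males aged
#'   `child_age_cutoff` or over.
#' @param acclimatization_effect Additional sweat rate when acclimatized.
#' @param age_slope Change in sweat rate per year of age (negative).
#' @param child_age_cutoff Age in years below which the sexes share a sweat
#'   rate.
#' @param floor Lower clamp on the predicted rate, g.min^-1.m^-2.
#'
#' @return An object of class `sweat_model`.
#' @export
sweat_model <- function(intercept = 7.39,
                        male_effect = 2.61,
                        acclimatization_effect = 1.16,
                        age_slope = -0.07,
                        child_age_cutoff = 14,
                        floor = 0.5) {
  stopifnot(child_age_cutoff >= 0, floor >= 0)
  structure(
    list(
      intercept = intercept,
      male_effect = male_effect,
      acclimatization_effect = acclimatization_effect,
      age_slope = age_slope,
      child_age_cutoff = child_age_cutoff,
      floor = floor
    ),
    class = "sweat_model"
  )
}

#' Allometric metabolic-rate model
#'
#' Metabolic rate is anchored at a 70 kg reference individual (125 W at
#' rest, 225 W during minimal exertion, 600 W during moderate exertion,
#' 1280 W during heavy exertion) and scaled with body mass as
#' `(mass / reference_mass)^mass_exponent`. The default exponent 0.75 is
#' the classic metabolic allometry; set it to 1 for linear scaling.
#'
#' @param reference_mass Anchor mass, kg.
#' @param rest,minimal,moderate,heavy Metabolic rate anchors at
#'   `reference_mass`, W.
#' @param mass_exponent Allometric scaling exponent (dimensionless).
#'
#' @return An object of class `metabolic_model`.
#' @export
metabolic_model <- function(reference_mass = 70,
                            rest = 125,
                            minimal = 225,
                            moderate = 600,
                            heavy = 1280,
                            mass_exponent = 0.75) {
  stopifnot(
    reference_mass > 0,
    rest > 0, minimal > rest, moderate > minimal, heavy > moderate
  )
  structure(
    list(
      reference_mass = reference_mass,
      anchors = c(rest = rest, minimal = minimal,
                  moderate = moderate, heavy = heavy),
      mass_exponent = mass_exponent
    ),
    class = "metabolic_model"
  )
}

#' Bundle of all model components
#'
#' Convenience container passed to the population-level functions so a
#' single object carries clothing, heat-balance, sweat, and metabolic
#' parameterizations.
#'
#' @param clothing A [clothing_parameters()] object.
#' @param heat A [heat_balance_config()] object.
#' @param sweat A [sweat_model()] object.
#' @param metabolic A [metabolic_model()] object.
#'
#' @return An object of class `manmo_models`.
#' @export
#' @examples
#' m <- manmo_models(heat = heat_balance_config(risk_threshold = 1.5))
manmo_models <- function(clothing = clothing_parameters(),
                         heat = heat_balance_config(),
                         sweat = sweat_model(),
                         metabolic = metabolic_model()) {
  stopifnot(
    inherits(clothing, "clothing_parameters"),
    inherits(heat, "heat_balance_config"),
    inherits(sweat, "sweat_model"),
    inherits(metabolic, "metabolic_model")
  )
  structure(
    list(clothing = clothing, heat = heat, sweat = sweat,
         metabolic = metabolic),
    class = "manmo_models"
  )
}
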