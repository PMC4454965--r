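# Shared fixtures and independent oracles for the test suite.

default_models <- manmo_models()

# Independent numeric root-finder for the clothing-surface energy balance,
# used to cross-check the closed-form solve.
clothing_temperature_uniroot <- function(weather, clothing, config) {
  h_c <- convection_coefficient(weather$wind_speed, config)
  balance <- function(t_cl) {
    (clothing$skin_temperature - t_cl) / clothing$insulation -
      (h_c * (t_cl - weather$air_temperature) -
         (1 - clothing$clothing_albedo) * config$projected_area_fraction *
           weather$solar_radiation)
  }
  stats::uniroot(balance, interval = c(-100, 200), tol = 1e-10)$root
}

# Brute-force per-individual risk computation: enumerates every individual
# x exposure cell, evaluates the full heat-balance model via
# heat_storage(), and aggregates at-risk weight per stratum and cell.
# Independent of the vectorized person-type path.
brute_force_risk <- function(individuals, exposure_distribution, record,
                             models = default_models) {
  rows <- list()
  for (i in seq_len(nrow(individuals))) {
    ind <- individuals[i, ]
    cells <- exposure_distribution[
      exposure_distribution$age_group == ind$age_group &
        exposure_distribution$sex == ind$sex, ]
    for (j in seq_len(nrow(cells))) {
      cell <- cells[j, ]
      at_risk <- FALSE
      if (cell$exposure != "not_exposed") {
        weather <- to_exposure_weather(record, cell$exposure)
        age_rep <- age_group_midpoint(ind$age_group)
        sweat_bin <- floor(max_sweat_rate(age_rep, ind$sex, TRUE,
                                          models$sweat) / 2) * 2 + 1
        body <- build_body_profile(
          age = age_rep, sex = ind$sex, mass = ind$mass_kg,
          height = ind$height_cm, exertion = cell$exertion,
          models = models, max_sweat_rate = sweat_bin
        )
        flux <- heat_storage(weather, body, models$clothing, models$heat)
        at_risk <- is_at_risk(flux$hourly_temp_gain, models$heat)
      }
      rows[[length(rows) + 1]] <- data.frame(
        age_group = ind$age_group, sex = ind$sex,
        cell = ifelse(cell$exposure == "not_exposed", "not_exposed",
                      paste(cell$exposure,
                            ifelse(cell$exertion %in% c("rest", "minimal"),
                                   "rest_minimal", cell$exertion),
                            sep = ":")),
        weight = ind$weight * cell$weight,
        at_risk = ind$weight * cell$weight * at_risk,
        stringsAsFactors = FALSE
      )
    }
  }
  all <- do.call(rbind, rows)
  stats::aggregate(cbind(weight, at_risk) ~ age_group + sex + cell,
                   data = all, FUN = sum)
}

# Small population of individuals sitting exactly on bin representatives
# (height block midpoints 10 cm, mass block midpoints 20 kg).
on_bin_population <- function(n = 200, seed = 42) {
  set.seed(seed)
  strata <- expand.grid(age_group = c("35-44", "75+"),
                        sex = c("male", "female"),
                        stringsAsFactors = FALSE)
  idx <- sample(nrow(strata), n, replace = TRUE)
  data.frame(
    age_group = strata$age_group[idx],
    sex = strata$sex[idx],
    height_cm = sample(c(145, 155, 165, 175), n, replace = TRUE),
    mass_kg = sample(c(50, 70, 90), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# Convert an individual listing into the population-table schema
# (per-stratum proportions at each height-mass pair).
individuals_to_population_table <- function(individuals) {
  counts <- stats::aggregate(
    list(count = rep(1, nrow(individuals))),
    by = individuals[c("age_group", "sex", "height_cm", "mass_kg")],
    FUN = sum
  )
  totals <- stats::aggregate(count ~ age_group + sex, data = counts,
                             FUN = sum)
  names(totals)[3] <- "stratum_n"
  merged <- merge(counts, totals)
  merged$proportion <- merged$count / merged$stratum_n
  merged[c("age_group", "sex", "height_cm", "mass_kg", "proportion")]
}

# Exposure distribution used by the oracle-equivalence tests: every
# stratum mixes outdoor heavy work, indoor desk work, indoor domestic
# work, and a fully protected remainder.
oracle_exposure_distribution <- function() {
  occ <- expand.grid(
    age_group = c("35-44", "75+"), sex = c("male", "female"),
    occupation = c("construction", "office_clerical", "home_duties",
                   "protected"),
    stringsAsFactors = FALSE
  )
  shares <- c(construction = 0.3, office_clerical = 0.4,
              home_duties = 0.2, protected = 0.1)
  occ$proportion <- unname(shares[occ$occupation])
  assign_exposure_exertion(occ)
}

# Default synthetic person-type suite used by several tests.
default_person_types <- local({
  gen <- generator_config()
  build_person_types(
    discretize_body_distribution(generate_population_table(gen)),
    assign_exposure_exertion(generate_occupation_table(gen), gen$mapping),
    default_models
  )
})

random_weather <- function(n, seed = 1) {
  set.seed(seed)
  weather_conditions(
    air_temperature = stats::runif(n, -10, 55),
    relative_humidity = stats::runif(n),
    solar_radiation = stats::runif(n, 0, 1100),
    wind_speed = stats::runif(n, 0.05, 10)
  )
}
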