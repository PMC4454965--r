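# Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default anthropometric distribution parameters
#'
#' Height means/SDs (cm) and log-normal BMI parameters per age group and
#' sex, approximating the shape of Australian adult distributions (e.g.
#' adult male height around 175 cm SD 7, female 162 cm SD 6.5, BMI median
#' around 26 declining in the oldest band). These are configuration values
#' describing a plausible population, not estimates of any survey.
#'
#' @return A data frame with columns `age_group`, `sex`, `height_mean`,
#'   `height_sd`, `bmi_log_median`, `bmi_log_sd`.
#' @export
default_anthropometry <- function() {
  groups <- default_age_groups()
  male <- data.frame(
    age_group = groups, sex = "male",
    height_mean = c(95, 141, 177, 177, 176, 175, 174, 172, 169),
    height_sd = c(12, 15, 7, 7, 7, 7, 7, 7, 7),
    bmi_median = c(16.5, 17.5, 24.5, 26, 27, 27.5, 27.5, 27, 26),
    bmi_log_sd = c(0.10, 0.15, 0.17, 0.18, 0.18, 0.18, 0.17, 0.16, 0.15),
    stringsAsFactors = FALSE
  )
  female <- data.frame(
    age_group = groups, sex = "female",
    height_mean = c(94, 140, 163, 163, 162, 161, 160, 158, 156),
    height_sd = c(12, 15, 6.5, 6.5, 6.5, 6.5, 6.5, 6.5, 6.5),
    bmi_median = c(16.5, 17.5, 23.5, 25, 26, 27, 27, 26.5, 25.5),
    bmi_log_sd = c(0.10, 0.15, 0.18, 0.19, 0.19, 0.19, 0.18, 0.17, 0.16),
    stringsAsFactors = FALSE
  )
  rbind(male, female)
}

#' Default occupation share table
#'
#' Occupation shares per age-sex stratum for a ~14-category occupation
#' list collapsed from the usual detailed classifications. Shares are
#' chosen so that, under [default_occupation_mapping()], roughly four
#' times more males than females are engaged in moderate-or-heavy
#' exertion outdoors among those aged 15 and over, while children's
#' strata contain no heavy-exertion categories.
#'
#' @return A data frame with columns `age_group`, `sex`, `occupation`,
#'   `proportion` (summing to 1 within each stratum).
#' @export
default_occupation_shares <- function() {
  row <- function(age_group, sex, shares) {
    data.frame(age_group = age_group, sex = sex,
               occupation = names(shares),
               proportion = unname(shares),
               stringsAsFactors = FALSE)
  }
  adult_male <- c(office_clerical = 0.24, retail_services = 0.12,
                  health_education = 0.06, manufacturing = 0.14,
                  construction = 0.12, agriculture = 0.04,
                  transport = 0.08, home_duties = 0.02,
                  not_employed = 0.08, protected = 0.10)
  adult_female <- c(office_clerical = 0.26, retail_services = 0.16,
                    health_education = 0.18, manufacturing = 0.05,
                    construction = 0.008, agriculture = 0.032,
                    transport = 0.02, home_duties = 0.14,
                    not_employed = 0.06, protected = 0.09)
  out <- rbind(
    row("0-4", "male", c(preschool_child = 0.95, outdoor_play = 0.05)),
    row("0-4", "female", c(preschool_child = 0.95, outdoor_play = 0.05)),
    row("5-14", "male", c(student = 0.80, outdoor_play = 0.20)),
    row("5-14", "female", c(student = 0.80, outdoor_play = 0.20)),
    row("15-24", "male",
        c(office_clerical = 0.15, retail_services = 0.20,
          health_education = 0.05, manufacturing = 0.10,
          construction = 0.10, agriculture = 0.04, transport = 0.05,
          student = 0.15, not_employed = 0.06, protected = 0.10)),
    row("15-24", "female",
        c(office_clerical = 0.20, retail_services = 0.25,
          health_education = 0.10, manufacturing = 0.04,
          construction = 0.005, agriculture = 0.03, transport = 0.01,
          student = 0.18, not_employed = 0.06, protected = 0.10,
          home_duties = 0.025)),
    row("25-34", "male", adult_male),
    row("25-34", "female", adult_female),
    row("35-44", "male", adult_male),
    row("35-44", "female", adult_female),
    row("45-54", "male", adult_male),
    row("45-54", "female", adult_female),
    row("55-64", "male",
        c(office_clerical = 0.18, retail_services = 0.08,
          health_education = 0.04, manufacturing = 0.10,
          construction = 0.09, agriculture = 0.03, transport = 0.06,
          home_duties = 0.04, retired = 0.20, not_employed = 0.08,
          protected = 0.10)),
    row("55-64", "female",
        c(office_clerical = 0.16, retail_services = 0.10,
          health_education = 0.12, manufacturing = 0.03,
          construction = 0.006, agriculture = 0.024, transport = 0.01,
          home_duties = 0.20, retired = 0.22, not_employed = 0.04,
          protected = 0.09)),
    row("65-74", "male",
        c(retired = 0.55, home_duties = 0.12, office_clerical = 0.04,
          agriculture = 0.02, transport = 0.02, protected = 0.25)),
    row("65-74", "female",
        c(retired = 0.55, home_duties = 0.18, office_clerical = 0.02,
          agriculture = 0.005, protected = 0.245)),
    row("75+", "male",
        c(retired = 0.63, home_duties = 0.22, protected = 0.15)),
    row("75+", "female",
        c(retired = 0.55, home_duties = 0.30, protected = 0.15))
  )
  rownames(out) <- NULL
  out
}

#' Default occupation to exposure/exertion mapping
#'
#' Editable table translating each occupation category into a weather
#' exposure (`not_exposed`, `indoors`, `outdoors`) and an exertion level
#' (`rest`, `minimal`, `moderate`, `heavy`): construction and agriculture
#' are outdoor heavy/moderate work, office and retail are indoor minimal,
#' domestic work and health/education are indoor moderate, retirees and
#' the non-employed are indoors at rest, and a `protected` category stands
#' for people able to fully modify their exposure (air conditioning,
#' deliberate avoidance).
#'
#' @return A data frame with columns `occupation`, `exposure`, `exertion`.
#' @export
default_occupation_mapping <- function() {
  data.frame(
    occupation = c("preschool_child", "student", "outdoor_play",
                   "office_clerical", "retail_services",
                   "health_education", "manufacturing", "construction",
                   "agriculture", "transport", "home_duties", "retired",
                   "not_employed", "protected"),
    exposure = c("indoors", "indoors", "outdoors",
                 "indoors", "indoors",
                 "indoors", "indoors", "outdoors",
                 "outdoors", "outdoors", "indoors", "indoors",
                 "indoors", "not_exposed"),
    exertion = c("rest", "minimal", "moderate",
                 "minimal", "minimal",
                 "moderate", "moderate", "heavy",
                 "moderate", "minimal", "moderate", "rest",
                 "rest", "rest"),
    stringsAsFactors = FALSE
  )
}

#' Configuration of the synthetic table generators
#'
#' @param seed Integer seed fixing all generator output.
#' @param age_group_shares Named numeric vector of population shares per
#'   age group (summing to 1).
#' @param sex_split Fraction of each age group that is male.
#' @param anthropometry Distribution parameter table, see
#'   [default_anthropometry()].
#' @param height_bmi_correlation Correlation between height and log-BMI
#'   within a stratum.
#' @param population_per_stratum Number of individuals sampled per
#'   age-sex stratum when tabulating height-mass pairs.
#' @param occupation_shares Occupation share table, see
#'   [default_occupation_shares()].
#' @param mapping Occupation mapping, see [default_occupation_mapping()].
#' @param outdoor_ratio_target Target male:female weight ratio in outdoor
#'   moderate-or-heavy cells among those aged 15+.
#' @param outdoor_ratio_tolerance Relative tolerance on the target.
#' @param n_days Length of the generated summer weather series.
#' @param start_date First date of the series.
#' @param spike_days Indices of heatwave days; the first is guaranteed to
#'   hold the series maximum temperature.
#' @param base_temperature,temperature_amplitude,temperature_noise_sd
#'   Seasonal sinusoid parameters for air temperature, degrees C.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(seed = 20140116,
                             age_group_shares = c(
                               "0-4" = 0.06, "5-14" = 0.12,
                               "15-24" = 0.13, "25-34" = 0.14,
                               "35-44" = 0.14, "45-54" = 0.13,
                               "55-64" = 0.12, "65-74" = 0.09,
                               "75+" = 0.07),
                             sex_split = 0.5,
                             anthropometry = default_anthropometry(),
                             height_bmi_correlation = 0.1,
                             population_per_stratum = 400,
                             occupation_shares = default_occupation_shares(),
                             mapping = default_occupation_mapping(),
                             outdoor_ratio_target = 4,
                             outdoor_ratio_tolerance = 0.05,
                             n_days = 59,
                             start_date = "2014-01-01",
                             spike_days = c(16, 17, 45),
                             base_temperature = 27,
                             temperature_amplitude = 5,
                             temperature_noise_sd = 2.5) {
  if (abs(sum(age_group_shares) - 1) > 1e-6) {
    stop("age_group_shares must sum to 1", call. = FALSE)
  }
  if (any(anthropometry$height_sd <= 0) || any(anthropometry$bmi_log_sd <= 0)) {
    stop("distribution SDs must be positive", call. = FALSE)
  }
  if (abs(height_bmi_correlation) >= 1) {
    stop("height_bmi_correlation must lie in (-1, 1)", call. = FALSE)
  }
  structure(
    list(
      seed = seed,
      age_group_shares = age_group_shares,
      sex_split = sex_split,
      anthropometry = anthropometry,
      height_bmi_correlation = height_bmi_correlation,
      population_per_stratum = population_per_stratum,
      occupation_shares = occupation_shares,
      mapping = mapping,
      outdoor_ratio_target = outdoor_ratio_target,
      outdoor_ratio_tolerance = outdoor_ratio_tolerance,
      n_days = n_days,
      start_date = start_date,
      spike_days = spike_days,
      base_temperature = base_temperature,
      temperature_amplitude = temperature_amplitude,
      temperature_noise_sd = temperature_noise_sd
    ),
    class = "generator_config"
  )
}

#' Generate a synthetic height-mass population table
#'
#' Samples individuals per age-sex stratum (heights Normal, BMI
#' log-normal with configurable correlation to height, mass = BMI x
#' height^2), rounds to whole centimetres and kilograms, and tabulates the
#' proportion of the stratum at each height-mass pair — the shape of a
#' census-style custom report. Fully deterministic given the seed.
#'
#' @param config A [generator_config()].
#' @return A data frame with columns `age_group`, `sex`, `height_cm`,
#'   `mass_kg`, `proportion`.
#' @export
#' @examples
#' pop <- generate_population_table(generator_config(seed = 1))
#' head(pop)
generate_population_table <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  anth <- config$anthropometry
  n <- config$population_per_stratum
  rho <- config$height_bmi_correlation
  with_seed(config$seed, {
    strata <- lapply(seq_len(nrow(anth)), function(i) {
      z1 <- stats::rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
      height <- anth$height_mean[i] + anth$height_sd[i] * z1
      bmi <- exp(log(anth$bmi_median[i]) + anth$bmi_log_sd[i] * z2)
      height <- pmax(round(height), 45)
      mass <- pmax(round(bmi * (height / 100)^2), 3)
      counts <- stats::aggregate(
        list(count = rep(1, n)),
        by = list(height_cm = height, mass_kg = mass), FUN = sum
      )
      data.frame(
        age_group = anth$age_group[i], sex = anth$sex[i],
        height_cm = counts$height_cm, mass_kg = counts$mass_kg,
        proportion = counts$count / n,
        stringsAsFactors = FALSE
      )
    })
    out <- do.call(rbind, strata)
    rownames(out) <- NULL
    out
  })
}

# Male:female weight ratio in outdoor moderate-or-heavy cells among
# age-15+ strata, given occupation shares, a mapping, and stratum shares.
outdoor_exertion_ratio <- function(occupation_table, mapping,
                                   age_group_shares, sex_split) {
  dist <- assign_exposure_exertion(occupation_table, mapping)
  adult <- dist[age_group_midpoint(dist$age_group) >= 15 &
                  dist$exposure == "outdoors" &
                  dist$exertion %in% c("moderate", "heavy"), ]
  share <- age_group_shares[adult$age_group] *
    ifelse(adult$sex == "male", sex_split, 1 - sex_split)
  weights <- adult$weight * share
  sum(weights[adult$sex == "male"]) / sum(weights[adult$sex == "female"])
}

#' Generate a synthetic occupation table
#'
#' Emits the configured occupation shares per age-sex stratum after
#' verifying that, under the configured mapping, the male:female weight
#' ratio in outdoor moderate-or-heavy cells among those aged 15 and over
#' matches the configured target (default 4) within tolerance. An
#' infeasible target is a configuration error.
#'
#' @param config A [generator_config()].
#' @return A data frame with columns `age_group`, `sex`, `occupation`,
#'   `proportion`.
#' @export
generate_occupation_table <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  occ <- config$occupation_shares
  check_stratum_sums(occ, "proportion", "occupation")
  ratio <- outdoor_exertion_ratio(occ, config$mapping,
                                  config$age_group_shares,
                                  config$sex_split)
  rel <- abs(ratio - config$outdoor_ratio_target) /
    config$outdoor_ratio_target
  if (rel > config$outdoor_ratio_tolerance) {
    stop(sprintf(
      paste0("occupation shares give an outdoor moderate/heavy male:female ",
             "ratio of %.2f, outside %.0f%% of the target %.2f"),
      ratio, 100 * config$outdoor_ratio_tolerance,
      config$outdoor_ratio_target), call. = FALSE)
  }
  occ
}

#' Generate a synthetic summer weather series
#'
#' Seeded sinusoid-plus-noise afternoon series over the configured summer
#' window, with heatwave spikes on the configured days; the first spike
#' day always carries the series maximum temperature. Humidity falls and
#' solar radiation rises on hotter days, mimicking dry continental heat.
#' All rows satisfy the validation rules of [read_weather_csv()].
#'
#' @param config A [generator_config()].
#' @return A weather record data frame (schema of [read_weather_csv()]).
#' @export
generate_weather_series <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_days
  if (any(config$spike_days < 1 | config$spike_days > n)) {
    stop("spike_days must lie within the series", call. = FALSE)
  }
  with_seed(config$seed + 1L, {
    day <- seq_len(n)
    temp <- config$base_temperature +
      config$temperature_amplitude * sin(2 * pi * (day - 10) / 45) +
      stats::rnorm(n, sd = config$temperature_noise_sd)
    spikes <- config$spike_days
    if (length(spikes) > 0) {
      peak <- max(temp[-spikes])
      temp[spikes] <- peak + seq(6, 3, length.out = length(spikes))
    }
    temp <- pmin(pmax(round(temp, 1), 10), 50)
    humidity <- 55 - 1.2 * (temp - config$base_temperature) +
      stats::rnorm(n, sd = 8)
    humidity <- round(pmin(pmax(humidity, 5), 95))
    solar <- 620 + 12 * (temp - config$base_temperature) +
      stats::rnorm(n, sd = 60)
    solar <- round(pmin(pmax(solar, 50), 1000))
    data.frame(
      date = format(as.Date(config$start_date) + day - 1),
      station = "Synthville",
      air_temperature = temp,
      relative_humidity = humidity,
      solar_radiation = solar,
      stringsAsFactors = FALSE
    )
  })
}
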