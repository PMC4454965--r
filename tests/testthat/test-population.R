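test_that("body discretization maps pairs to block midpoints and conserves mass", {
  single <- data.frame(age_group = "35-44", sex = "female",
                       height_cm = 162, mass_kg = 64, proportion = 1)
  out <- discretize_body_distribution(single)
  expect_equal(nrow(out), 1)
  expect_equal(out$height_bin, 165)
  expect_equal(out$mass_bin, 70)
  expect_equal(out$weight, 1)

  # two pairs falling in the same 10 cm x 20 kg block merge
  pair <- data.frame(age_group = "35-44", sex = "female",
                     height_cm = c(161, 168), mass_kg = c(61, 75),
                     proportion = c(0.4, 0.6))
  out <- discretize_body_distribution(pair)
  expect_equal(nrow(out), 1)
  expect_equal(out$weight, 1)

  # conservation on a random synthetic table, stratum by stratum
  pop <- generate_population_table(generator_config(seed = 11))
  binned <- discretize_body_distribution(pop)
  before <- aggregate(proportion ~ age_group + sex, data = pop, FUN = sum)
  after <- aggregate(weight ~ age_group + sex, data = binned, FUN = sum)
  merged <- merge(before, after)
  expect_equal(merged$proportion, merged$weight, tolerance = 1e-9)

  bad <- single
  bad$proportion <- 0.7
  expect_error(discretize_body_distribution(bad), "sum to 1")
  bad$proportion <- -0.1
  expect_error(discretize_body_distribution(bad), "non-negative")
})

test_that("occupation shares translate into exposure-exertion distributions", {
  occ <- data.frame(age_group = "25-34", sex = "male",
                    occupation = "office_clerical", proportion = 1)
  dist <- assign_exposure_exertion(occ)
  expect_equal(nrow(dist), 1)
  expect_equal(dist$exposure, "indoors")
  expect_equal(dist$exertion, "minimal")
  expect_equal(dist$weight, 1)

  full <- assign_exposure_exertion(generate_occupation_table(
    generator_config(seed = 3)))
  sums <- aggregate(weight ~ age_group + sex, data = full, FUN = sum)
  expect_equal(sums$weight, rep(1, nrow(sums)), tolerance = 1e-9)

  unknown <- data.frame(age_group = "25-34", sex = "male",
                        occupation = "astronaut", proportion = 1)
  expect_error(assign_exposure_exertion(unknown), "absent from")
})

test_that("person-types cross bins with exposure cells and conserve weight", {
  binned <- data.frame(age_group = "35-44", sex = "female",
                       height_bin = 165, mass_bin = 70, weight = 1)
  dist <- data.frame(age_group = "35-44", sex = "female",
                     exposure = c("indoors", "outdoors"),
                     exertion = c("minimal", "moderate"),
                     weight = c(0.7, 0.3))
  pt <- build_person_types(binned, dist)
  expect_equal(nrow(pt), 2)
  expect_equal(sort(pt$weight), c(0.3, 0.7))
  expect_equal(sum(pt$weight), 1)
  # stratum sweat rate is the 2-unit bin midpoint at the representative age
  raw <- max_sweat_rate(40, "female")
  expect_equal(unique(pt$sweat_bin), floor(raw / 2) * 2 + 1)

  # conservation over the full synthetic population
  gen <- generator_config(seed = 5)
  pt <- build_person_types(
    discretize_body_distribution(generate_population_table(gen)),
    assign_exposure_exertion(generate_occupation_table(gen), gen$mapping)
  )
  sums <- aggregate(weight ~ age_group + sex, data = pt, FUN = sum)
  expect_equal(sums$weight, rep(1, nrow(sums)), tolerance = 1e-9)
  # far fewer person-types than the individuals they represent
  expect_lt(nrow(pt),
            gen$population_per_stratum * length(unique(paste(pt$age_group,
                                                             pt$sex))))
})

test_that("representative ages are band midpoints with 80 for the open band", {
  expect_equal(age_group_midpoint(c("0-4", "5-14", "15-24", "75+")),
               c(2.5, 10, 20, 80))
  expect_error(age_group_midpoint("old"), "unparseable")
})

test_that("mild weather puts no one at risk and risk rises with temperature", {
  pt <- default_person_types
  mild <- data.frame(date = "d", station = "s", air_temperature = 10,
                     relative_humidity = 50, solar_radiation = 0)
  out <- population_risk(pt, mild)
  # all rest and minimal-exertion cells are safe; a weather-independent
  # residual remains in moderate/heavy cells whose metabolic load exceeds
  # the individual's maximal dissipation (sweat-capped evaporation plus
  # the fixed skin-temperature gradient)
  expect_true(all(out$at_risk[grepl("rest_minimal|not_exposed",
                                    out$cell)] == 0))
  risky <- out$cell[out$at_risk > 0]
  expect_true(all(grepl("moderate|heavy", risky)))

  # heating the same day never lowers any stratum's total risk
  totals <- lapply(c(24, 30, 36, 42, 48), function(t_a) {
    record <- data.frame(date = "d", station = "s", air_temperature = t_a,
                         relative_humidity = 30, solar_radiation = 500)
    tot <- risk_totals(population_risk(pt, record))
    tot[order(tot$age_group, tot$sex), "total_at_risk"]
  })
  for (i in seq_len(length(totals) - 1)) {
    expect_true(all(totals[[i + 1]] >= totals[[i]] - 1e-12))
  }
})

test_that("breakdowns are additive and the not-exposed cell is riskless", {
  pt <- default_person_types
  melbourne <- builtin_city_fixtures()[2, ]
  out <- population_risk(pt, melbourne)
  expect_true(all(out$at_risk[out$cell == "not_exposed"] == 0))
  expect_true(all(out$at_risk >= 0 & out$at_risk <= 1))
  # per-cell weights sum to 1 and at-risk never exceeds the cell weight
  sums <- aggregate(cbind(weight, at_risk) ~ age_group + sex, data = out,
                    FUN = sum)
  expect_equal(sums$weight, rep(1, nrow(sums)), tolerance = 1e-9)
  expect_true(all(out$at_risk <= out$weight + 1e-12))
  # totals equal the cell sums by construction of risk_totals
  tot <- risk_totals(out)
  expect_equal(sort(tot$total_at_risk), sort(sums$at_risk), tolerance = 1e-12)
})

test_that("binned aggregation equals exhaustive per-individual enumeration", {
  individuals <- on_bin_population(n = 200, seed = 42)
  pop_table <- individuals_to_population_table(individuals)
  dist <- oracle_exposure_distribution()
  pt <- build_person_types(discretize_body_distribution(pop_table), dist)
  melbourne <- builtin_city_fixtures()[2, ]
  binned <- population_risk(pt, melbourne)
  binned <- binned[binned$weight > 0, ]

  # per-individual weights: 1 / stratum count
  counts <- table(paste(individuals$age_group, individuals$sex))
  individuals$weight <- 1 / as.numeric(counts[paste(individuals$age_group,
                                                    individuals$sex)])
  oracle <- brute_force_risk(individuals, dist, melbourne)
  merged <- merge(binned, oracle, by = c("age_group", "sex", "cell"),
                  suffixes = c("_binned", "_oracle"))
  expect_equal(nrow(merged), nrow(binned))
  expect_equal(merged$weight_binned, merged$weight_oracle, tolerance = 1e-9)
  expect_equal(merged$at_risk_binned, merged$at_risk_oracle,
               tolerance = 1e-9)
})

test_that("time series reduce to single-day runs and are deterministic", {
  pt <- default_person_types
  day <- builtin_city_fixtures()[1, ]
  series <- risk_time_series(pt, day)
  single <- population_risk(pt, day)
  expect_equal(series$at_risk, single$at_risk)
  expect_equal(series$cell, single$cell)

  two <- rbind(day, transform(day, date = "2014-01-29"))
  out <- risk_time_series(pt, two)
  first <- out[out$date == day$date, ]
  second <- out[out$date == "2014-01-29", ]
  expect_equal(first$at_risk, second$at_risk)
  expect_error(risk_time_series(pt, day[0, ]), "empty")
})
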