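#' Assemble a run configuration
#'
#' Validates the file paths and model overrides of a simulation run before
#' any computation happens. Overrides may come from a YAML file (see
#' [read_run_config()]) with individual arguments taking precedence.
#'
#' @param weather Path to a weather CSV (see [read_weather_csv()]).
#' @param population Path to a population CSV, or `NULL` to generate one
#'   synthetically from `seed`.
#' @param occupations Path to an occupation CSV, or `NULL` to use the
#'   synthetic default.
#' @param mapping Path to a YAML occupation mapping, or `NULL` for
#'   [default_occupation_mapping()].
#' @param threshold Risk threshold, degrees C per hour.
#' @param seed Seed for the synthetic generators.
#' @param out Output directory.
#' @param figures Logical; also write stacked-bar and time-series figures.
#' @param overrides Named list of model coefficient overrides; supported
#'   names are the arguments of [clothing_parameters()],
#'   [heat_balance_config()], [sweat_model()], and [metabolic_model()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(weather,
                       population = NULL,
                       occupations = NULL,
                       mapping = NULL,
                       threshold = 2.0,
                       seed = 20140116,
                       out = "heatstrain-output",
                       figures = FALSE,
                       overrides = list()) {
  for (path in c(weather, population, occupations, mapping)) {
    if (!is.null(path) && !file.exists(path)) {
      stop("input file not found: ", path, call. = FALSE)
    }
  }
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold <= 0) {
    stop("threshold must be a single positive number", call. = FALSE)
  }
  if (!is.list(overrides)) {
    stop("overrides must be a named list", call. = FALSE)
  }
  known <- c(names(formals(clothing_parameters)),
             names(formals(heat_balance_config)),
             names(formals(sweat_model)),
             names(formals(metabolic_model)))
  unknown <- setdiff(names(overrides), known)
  if (length(unknown) > 0) {
    stop("unknown model override(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(weather = weather, population = population,
         occupations = occupations, mapping = mapping,
         threshold = threshold, seed = seed, out = out,
         figures = figures, overrides = overrides),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' @param path Path to a YAML file whose keys are the arguments of
#'   [run_config()].
#' @param ... Overrides applied on top of the file's values.
#' @return An object of class `run_config`.
#' @export
read_run_config <- function(path, ...) {
  values <- yaml::read_yaml(path)
  dots <- list(...)
  values[names(dots)] <- dots
  do.call(run_config, values)
}

apply_overrides <- function(constructor, overrides) {
  args <- overrides[intersect(names(overrides), names(formals(constructor)))]
  do.call(constructor, args)
}

models_from_config <- function(config) {
  overrides <- config$overrides
  overrides$risk_threshold <- config$threshold
  manmo_models(
    clothing = apply_overrides(clothing_parameters, overrides),
    heat = apply_overrides(heat_balance_config, overrides),
    sweat = apply_overrides(sweat_model, overrides),
    metabolic = apply_overrides(metabolic_model, overrides)
  )
}

load_mapping <- function(path) {
  if (is.null(path)) {
    return(default_occupation_mapping())
  }
  raw <- yaml::read_yaml(path)
  data.frame(
    occupation = names(raw),
    exposure = vapply(raw, function(x) x$exposure, character(1)),
    exertion = vapply(raw, function(x) x$exertion, character(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Run the full population heat-strain simulation
#'
#' Loads (or synthesizes) the population, occupation, and weather inputs,
#' builds the weighted person-types, evaluates the daily risk breakdowns,
#' and writes a tidy risk CSV plus a JSON summary (and figures when
#' requested) to the output directory. All effective parameter values are
#' recorded in the JSON metadata. Any validation failure aborts before
#' computation with no partial outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the breakdown table and output paths.
#' @export
run_simulation <- function(config) {
  stopifnot(inherits(config, "run_config"))
  weather <- read_weather_csv(config$weather)
  if (nrow(weather) == 0) {
    stop("weather file contains no observations", call. = FALSE)
  }
  gen <- generator_config(seed = config$seed)
  population <- if (is.null(config$population)) {
    generate_population_table(gen)
  } else {
    utils::read.csv(config$population, stringsAsFactors = FALSE)
  }
  occupations <- if (is.null(config$occupations)) {
    generate_occupation_table(gen)
  } else {
    utils::read.csv(config$occupations, stringsAsFactors = FALSE)
  }
  mapping <- load_mapping(config$mapping)
  models <- models_from_config(config)

  person_types <- build_person_types(
    discretize_body_distribution(population),
    assign_exposure_exertion(occupations, mapping),
    models
  )
  breakdown <- risk_time_series(person_types, weather, models)

  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  paths <- write_risk_report(
    breakdown, config$out,
    metadata = list(
      seed = config$seed,
      threshold = config$threshold,
      weather = config$weather,
      population = config$population,
      occupations = config$occupations,
      config_hash = unname(tools::md5sum(config$weather)),
      n_person_types = nrow(person_types),
      package_version = as.character(utils::packageVersion("heatstrain")),
      effective_parameters = list(
        clothing = unclass(models$clothing),
        heat = unclass(models$heat),
        sweat = unclass(models$sweat),
        metabolic = as.list(c(
          reference_mass = models$metabolic$reference_mass,
          models$metabolic$anchors,
          mass_exponent = models$metabolic$mass_exponent))
      )
    )
  )
  if (isTRUE(config$figures)) {
    for (st in unique(breakdown$station)) {
      sub <- breakdown[breakdown$station == st, ]
      if (length(unique(sub$date)) == 1) {
        p <- plot_risk_bars(sub, title = paste0(
          st, " ", sub$date[1], " (", sub$air_temperature[1], " degC)"))
        ggplot2::ggsave(file.path(config$out,
                                  paste0("risk-bars-", st, ".png")),
                        p, width = 9, height = 5, dpi = 150)
      }
    }
    if (length(unique(breakdown$date)) > 1) {
      p <- plot_risk_series(breakdown)
      ggplot2::ggsave(file.path(config$out, "risk-series.png"), p,
                      width = 9, height = 6, dpi = 150)
    }
  }
  invisible(list(breakdown = breakdown, paths = paths))
}

#' Write a risk report to CSV and JSON
#'
#' @param breakdown A breakdown table from [population_risk()] or
#'   [risk_time_series()].
#' @param out Output directory (created if needed).
#' @param metadata Named list stored in the JSON summary alongside the
#'   per-stratum totals.
#' @return A named list of file paths.
#' @export
write_risk_report <- function(breakdown, out, metadata = list()) {
  if (nrow(breakdown) == 0) {
    stop("breakdown is empty", call. = FALSE)
  }
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(out, "risk.csv")
  printable <- breakdown
  for (col in intersect(c("weight", "at_risk"), names(printable))) {
    # full precision so a re-read reproduces proportions bit-exactly
    printable[[col]] <- sprintf("%.17g", printable[[col]])
  }
  utils::write.csv(printable, csv_path, row.names = FALSE)
  totals <- risk_totals(breakdown)
  json_path <- file.path(out, "summary.json")
  jsonlite::write_json(
    list(metadata = metadata, totals = totals),
    json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  list(csv = csv_path, json = json_path)
}

#' Temperature-humidity sweep of population risk
#'
#' Evaluates total at-risk proportions over a grid of air temperatures and
#' relative humidities at fixed solar radiation — the raw material for
#' threshold maps.
#'
#' @param person_types Output of [build_person_types()].
#' @param temperatures Air temperatures, degrees C.
#' @param humidities Relative humidities, %.
#' @param solar_radiation Solar radiation, W.m^-2.
#' @param models A [manmo_models()] bundle.
#' @return A data frame with one row per grid point and stratum.
#' @export
sweep_weather_grid <- function(person_types,
                               temperatures = seq(20, 45, by = 5),
                               humidities = c(20, 50, 80),
                               solar_radiation = 600,
                               models = manmo_models()) {
  grid <- expand.grid(air_temperature = temperatures,
                      relative_humidity = humidities)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    record <- data.frame(
      date = sprintf("grid-%03d", i), station = "sweep",
      air_temperature = grid$air_temperature[i],
      relative_humidity = grid$relative_humidity[i],
      solar_radiation = solar_radiation
    )
    totals <- risk_totals(population_risk(person_types, record, models))
    cbind(grid[rep(i, nrow(totals)), , drop = FALSE], totals,
          row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Stacked-bar figure of a single-day risk breakdown
#'
#' One bar per age-sex stratum, stacked by exposure-exertion cell, bar
#' height equal to the proportion of the stratum at risk.
#'
#' @param breakdown A single-day breakdown from [population_risk()].
#' @param title Plot title.
#' @return A ggplot object.
#' @export
plot_risk_bars <- function(breakdown, title = "Proportion at risk") {
  d <- breakdown[breakdown$at_risk > 0, , drop = FALSE]
  if (nrow(d) == 0) {
    d <- breakdown[1, , drop = FALSE]
    d$at_risk <- 0
  }
  d$age_group <- factor(d$age_group, levels = default_age_groups())
  ggplot2::ggplot(d, ggplot2::aes(x = .data$age_group, y = .data$at_risk,
                                  fill = .data$cell)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~sex) +
    ggplot2::labs(x = "Age group", y = "Proportion of group at risk",
                  fill = "Exposure / exertion", title = title) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Time-series figure of daily risk with driving temperature
#'
#' @param breakdown Output of [risk_time_series()].
#' @param age_group,sexes Strata to plot (default the oldest band, both
#'   sexes).
#' @return A ggplot object.
#' @export
plot_risk_series <- function(breakdown, age_group = "75+",
                             sexes = c("female", "male")) {
  d <- breakdown[breakdown$age_group == age_group &
                   breakdown$sex %in% sexes &
                   breakdown$cell != "not_exposed", , drop = FALSE]
  d$date <- as.Date(d$date)
  scale <- max(d$air_temperature) /
    max(max(tapply(d$at_risk, list(d$date, d$sex), sum), na.rm = TRUE),
        0.05)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$date)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$at_risk, fill = .data$cell)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$air_temperature / scale),
                       colour = "black") +
    ggplot2::facet_wrap(~sex, ncol = 1) +
    ggplot2::scale_y_continuous(
      name = "Proportion of group at risk",
      sec.axis = ggplot2::sec_axis(~ . * scale,
                                   name = "Air temperature (degC)")) +
    ggplot2::labs(x = NULL, fill = "Exposure / exertion",
                  title = paste("Daily heat-strain risk,", age_group)) +
    ggplot2::theme_minimal()
}
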