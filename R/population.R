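# Block widths used to discretize continuous individual characteristics
# into person-type bins: 20 kg mass, 10 cm height, 2 g.min^-1.m^-2 sweat.
MASS_BIN_KG <- 20
HEIGHT_BIN_CM <- 10
SWEAT_BIN <- 2

# Midpoint of the block of the given width that contains x; open-ended top
# bins inherit the same rule (lower edge + half width).
bin_midpoint <- function(x, width) {
  floor(x / width) * width + width / 2
}

#' Representative age of an age-group label
#'
#' Age enters the sweat model as the representative age of the person's
#' age band: the arithmetic midpoint of closed bands (`"15-24"` gives 20)
#' and lower edge plus half a band width for the open-ended top band
#' (`"75+"` gives 80).
#'
#' @param age_group Character vector of labels like `"0-4"`, `"15-24"`,
#'   `"75+"`.
#' @return Numeric representative ages.
#' @export
#' @examples
#' age_group_midpoint(c("0-4", "15-24", "75+"))
age_group_midpoint <- function(age_group) {
  vapply(as.character(age_group), function(label) {
    if (grepl("\\+$", label)) {
      as.numeric(sub("\\+$", "", label)) + 5
    } else {
      bounds <- suppressWarnings(
        as.numeric(strsplit(label, "-", fixed = TRUE)[[1]]))
      if (length(bounds) != 2 || anyNA(bounds)) {
        stop("unparseable age group label: ", label, call. = FALSE)
      }
      (bounds[1] + bounds[2] + 1) / 2
    }
  }, numeric(1), USE.NAMES = FALSE)
}

#' Default age-group labels
#'
#' The age bands used throughout: `0-4`, `5-14`, then ten-year bands to
#' `65-74`, and `75+`.
#'
#' @return Character vector of labels.
#' @export
default_age_groups <- function() {
  c("0-4", "5-14", "15-24", "25-34", "35-44", "45-54", "55-64", "65-74",
    "75+")
}

check_stratum_sums <- function(tab, value_col, what) {
  if (any(tab[[value_col]] < 0)) {
    stop(what, " proportions must be non-negative", call. = FALSE)
  }
  sums <- stats::aggregate(tab[[value_col]],
                           by = list(age_group = tab$age_group,
                                     sex = tab$sex),
                           FUN = sum)
  off <- abs(sums$x - 1) > 1e-6
  if (any(off)) {
    bad <- paste(sums$age_group[off], sums$sex[off], sep = "/")
    stop(what, " proportions must sum to 1 within each age-sex stratum; ",
         "off in: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(tab)
}

#' Discretize a height-mass population table into body bins
#'
#' Maps each (height, mass) pair to its 10 cm x 20 kg block, represented
#' by the block midpoint, and sums proportions within blocks. Total weight
#' per age-sex stratum is conserved.
#'
#' @param population_table Data frame with columns `age_group`, `sex`,
#'   `height_cm`, `mass_kg`, `proportion`; proportions must be
#'   non-negative and sum to 1 within each age-sex stratum.
#' @return A data frame with columns `age_group`, `sex`, `height_bin`,
#'   `mass_bin` (block midpoints) and `weight`.
#' @export
discretize_body_distribution <- function(population_table) {
  required <- c("age_group", "sex", "height_cm", "mass_kg", "proportion")
  missing <- setdiff(required, names(population_table))
  if (length(missing) > 0) {
    stop("population table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_stratum_sums(population_table, "proportion", "population")
  binned <- data.frame(
    age_group = population_table$age_group,
    sex = population_table$sex,
    height_bin = bin_midpoint(population_table$height_cm, HEIGHT_BIN_CM),
    mass_bin = bin_midpoint(population_table$mass_kg, MASS_BIN_KG),
    weight = population_table$proportion,
    stringsAsFactors = FALSE
  )
  out <- stats::aggregate(
    weight ~ age_group + sex + height_bin + mass_bin,
    data = binned, FUN = sum
  )
  out[order(out$age_group, out$sex, out$height_bin, out$mass_bin), ,
      drop = FALSE]
}

#' Map occupations to a weather-exposure and exertion distribution
#'
#' Translates occupation shares per age-sex stratum into a probability
#' distribution over (exposure category x exertion level) using a mapping
#' table. Every occupation present in the table must appear in the
#' mapping.
#'
#' @param occupation_table Data frame with columns `age_group`, `sex`,
#'   `occupation`, `proportion`; shares sum to 1 per stratum.
#' @param mapping Data frame with columns `occupation`, `exposure`
#'   (`not_exposed`, `indoors`, `outdoors`) and `exertion` (`rest`,
#'   `minimal`, `moderate`, `heavy`). Defaults to
#'   [default_occupation_mapping()].
#' @return A data frame with columns `age_group`, `sex`, `exposure`,
#'   `exertion`, `weight`, with weights summing to 1 per stratum.
#' @export
assign_exposure_exertion <- function(occupation_table,
                                     mapping = default_occupation_mapping()) {
  required <- c("age_group", "sex", "occupation", "proportion")
  missing <- setdiff(required, names(occupation_table))
  if (length(missing) > 0) {
    stop("occupation table is missing columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_stratum_sums(occupation_table, "proportion", "occupation")
  unmapped <- setdiff(unique(occupation_table$occupation),
                      mapping$occupation)
  if (length(unmapped) > 0) {
    stop("occupations absent from the exposure mapping: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  merged <- merge(occupation_table, mapping, by = "occupation")
  out <- stats::aggregate(
    proportion ~ age_group + sex + exposure + exertion,
    data = merged, FUN = sum
  )
  names(out)[names(out) == "proportion"] <- "weight"
  out[order(out$age_group, out$sex, out$exposure, out$exertion), ,
      drop = FALSE]
}

#' Build the suite of weighted person-types
#'
#' Crosses the discretized body bins with the exposure-exertion
#' distribution of each age-sex stratum; weights multiply. The stratum's
#' maximal sweat rate is computed at its representative age
#' ([age_group_midpoint()]) and then discretized into 2-unit blocks like
#' the other continuous characteristics. Total weight per stratum equals
#' the stratum's share (1 unless `stratum_shares` is supplied).
#'
#' @param binned_population Output of [discretize_body_distribution()].
#' @param exposure_distribution Output of [assign_exposure_exertion()].
#' @param models A [manmo_models()] bundle (the sweat model is used).
#' @param acclimatized Logical, default `TRUE`.
#' @param stratum_shares Optional data frame `age_group`, `sex`, `share`
#'   rescaling each stratum's person-type weights to its population share.
#' @return A data frame of person-types: `age_group`, `sex`, `age_rep`,
#'   `height_bin`, `mass_bin`, `sweat_bin`, `exposure`, `exertion`,
#'   `weight`.
#' @export
build_person_types <- function(binned_population, exposure_distribution,
                               models = manmo_models(),
                               acclimatized = TRUE,
                               stratum_shares = NULL) {
  pt <- merge(binned_population, exposure_distribution,
              by = c("age_group", "sex"), suffixes = c("_body", "_exp"))
  if (nrow(pt) == 0) {
    stop("no overlap between population and occupation strata",
         call. = FALSE)
  }
  pt$weight <- pt$weight_body * pt$weight_exp
  pt$weight_body <- pt$weight_exp <- NULL
  pt$age_rep <- age_group_midpoint(pt$age_group)
  sweat <- max_sweat_rate(pt$age_rep, pt$sex, acclimatized, models$sweat)
  pt$sweat_bin <- bin_midpoint(sweat, SWEAT_BIN)
  if (!is.null(stratum_shares)) {
    pt <- merge(pt, stratum_shares, by = c("age_group", "sex"))
    pt$weight <- pt$weight * pt$share
    pt$share <- NULL
  }
  cols <- c("age_group", "sex", "age_rep", "height_bin", "mass_bin",
            "sweat_bin", "exposure", "exertion", "weight")
  pt <- pt[cols]
  pt <- pt[order(pt$age_group, pt$sex, pt$exposure, pt$exertion,
                 pt$height_bin, pt$mass_bin), , drop = FALSE]
  rownames(pt) <- NULL
  pt
}

# Reporting cell label: rest and minimal exertion are merged, and the
# not-exposed category is a single collapsed cell.
risk_cell_label <- function(exposure, exertion) {
  ifelse(exposure == "not_exposed", "not_exposed",
         paste(exposure,
               ifelse(exertion %in% c("rest", "minimal"),
                      "rest_minimal", exertion),
               sep = ":"))
}

#' All reporting cell labels
#'
#' The exposure-by-exertion cells used in risk breakdowns: indoors and
#' outdoors each at rest/minimal (merged), moderate, and heavy exertion,
#' plus the collapsed not-exposed cell.
#'
#' @return Character vector of cell labels.
#' @export
risk_cells <- function() {
  c(as.vector(outer(c("indoors", "outdoors"),
                    c("rest_minimal", "moderate", "heavy"),
                    function(e, x) paste(e, x, sep = ":"))),
    "not_exposed")
}

#' Population risk under one set of weather conditions
#'
#' Evaluates the heat-balance model for every person-type under the
#' exposure-modified weather (indoor or outdoor wind and solar assumptions)
#' and aggregates the weights of at-risk types into a per-stratum
#' breakdown. Not-exposed person-types are never at risk by definition.
#'
#' @param person_types Output of [build_person_types()].
#' @param record A one-row weather record (see [read_weather_csv()]).
#' @param models A [manmo_models()] bundle.
#' @return A data frame with one row per age-sex stratum and reporting
#'   cell: `age_group`, `sex`, `cell`, `weight` (cell weight as a fraction
#'   of the stratum), `at_risk` (at-risk weight as a fraction of the
#'   stratum); use [risk_totals()] to collapse over cells.
#' @export
#' @examples
#' \donttest{
#' pop <- generate_population_table(generator_config(seed = 1))
#' occ <- generate_occupation_table(generator_config(seed = 1))
#' pt <- build_person_types(discretize_body_distribution(pop),
#'                          assign_exposure_exertion(occ))
#' melbourne <- builtin_city_fixtures()[2, ]
#' head(population_risk(pt, melbourne))
#' }
population_risk <- function(person_types, record,
                            models = manmo_models()) {
  if (nrow(record) != 1) {
    stop("record must be a single weather observation", call. = FALSE)
  }
  pt <- person_types
  if (any(pt$weight < 0)) {
    stop("person-type weights must be non-negative", call. = FALSE)
  }
  pt$at_risk_flag <- FALSE
  for (exposure in c("indoors", "outdoors")) {
    idx <- which(pt$exposure == exposure)
    if (length(idx) == 0) next
    weather <- to_exposure_weather(record, exposure)
    parts <- storage_components(
      weather,
      surface_area = body_surface_area(pt$mass_bin[idx], pt$height_bin[idx]),
      max_sweat_rate = pt$sweat_bin[idx],
      metabolic_rate = metabolic_rate(pt$exertion[idx], pt$mass_bin[idx],
                                      models$metabolic),
      clothing = models$clothing, config = models$heat
    )
    gain <- hourly_temperature_gain(parts$storage, pt$mass_bin[idx],
                                    models$heat)
    pt$at_risk_flag[idx] <- is_at_risk(gain, models$heat)
  }
  pt$cell <- risk_cell_label(pt$exposure, pt$exertion)

  stratum_totals <- stats::aggregate(weight ~ age_group + sex, data = pt,
                                     FUN = sum)
  names(stratum_totals)[3] <- "stratum_weight"

  cell_weight <- stats::aggregate(weight ~ age_group + sex + cell,
                                  data = pt, FUN = sum)
  pt$risk_weight <- pt$weight * pt$at_risk_flag
  cell_risk <- stats::aggregate(risk_weight ~ age_group + sex + cell,
                                data = pt, FUN = sum)

  # complete the grid so every stratum reports every cell
  strata <- unique(pt[c("age_group", "sex")])
  grid <- merge(strata, data.frame(cell = risk_cells()))
  out <- merge(grid, cell_weight, by = c("age_group", "sex", "cell"),
               all.x = TRUE)
  out <- merge(out, cell_risk, by = c("age_group", "sex", "cell"),
               all.x = TRUE)
  out <- merge(out, stratum_totals, by = c("age_group", "sex"))
  out$weight[is.na(out$weight)] <- 0
  out$risk_weight[is.na(out$risk_weight)] <- 0
  out$weight <- out$weight / out$stratum_weight
  out$at_risk <- out$risk_weight / out$stratum_weight
  out$risk_weight <- out$stratum_weight <- NULL
  out <- out[order(out$age_group, out$sex, out$cell), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse a risk breakdown to per-stratum totals
#'
#' @param breakdown Output of [population_risk()] (optionally with extra
#'   grouping columns such as `date`).
#' @return A data frame with `total_at_risk` per age-sex stratum (and date
#'   when present).
#' @export
risk_totals <- function(breakdown) {
  keys <- intersect(c("date", "station", "age_group", "sex"),
                    names(breakdown))
  out <- stats::aggregate(breakdown["at_risk"], by = breakdown[keys],
                          FUN = sum)
  names(out)[names(out) == "at_risk"] <- "total_at_risk"
  out
}

#' Risk breakdowns over a weather series
#'
#' Runs [population_risk()] for each day of a weather series, echoing the
#' day's driving weather alongside each breakdown for plotting.
#'
#' @param person_types Output of [build_person_types()].
#' @param weather_series Data frame of weather records (see
#'   [read_weather_csv()]).
#' @param models A [manmo_models()] bundle.
#' @return A data frame of daily breakdowns with `date`, `station`,
#'   `air_temperature`, `relative_humidity`, `solar_radiation` columns
#'   prepended.
#' @export
risk_time_series <- function(person_types, weather_series,
                             models = manmo_models()) {
  if (nrow(weather_series) == 0) {
    stop("weather series is empty", call. = FALSE)
  }
  days <- lapply(seq_len(nrow(weather_series)), function(i) {
    record <- weather_series[i, , drop = FALSE]
    breakdown <- population_risk(person_types, record, models)
    cbind(
      record[rep(1, nrow(breakdown)),
             c("date", "station", "air_temperature", "relative_humidity",
               "solar_radiation"),
             drop = FALSE],
      breakdown,
      row.names = NULL
    )
  })
  do.call(rbind, days)
}
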