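#' Body surface area from mass and height
#'
#' The Du Bois formula,
#' `A = 0.007184 * mass^0.425 * height^0.725`, with mass in kg and height
#' in cm, giving surface area in m^2.
#'
#' @param mass Body mass, kg, positive.
#' @param height Height, cm, positive.
#' @return Surface area, m^2.
#' @export
#' @examples
#' body_surface_area(70, 170) # ~1.81 m^2
body_surface_area <- function(mass, height) {
  if (any(mass <= 0) || any(height <= 0)) {
    stop("mass and height must be positive", call. = FALSE)
  }
  0.007184 * mass^0.425 * height^0.725
}

#' Maximal sweat rate by age, sex, and acclimatization
#'
#' Linear model of maximal sweat production per unit skin area:
#' `intercept + male_effect * male + acclimatization_effect * acclimatized
#' + age_slope * age`. Below the child age cutoff (14 years) the male
#' indicator is forced to zero, since pre-pubescent boys sweat at the same
#' rate as girls. The prediction is clamped below at the configured floor.
#'
#' @param age Age in years, non-negative.
#' @param sex `"male"` or `"female"` (vectorized).
#' @param acclimatized Logical; all individuals are assumed acclimatized by
#'   default.
#' @param coefficients A [sweat_model()] object.
#' @return Maximal sweat rate, g.min^-1.m^-2.
#' @export
#' @examples
#' max_sweat_rate(0, "female", acclimatized = FALSE) # intercept, 7.39
#' max_sweat_rate(30, "male")                        # 9.06
#' max_sweat_rate(10, "male")                        # equals the female 7.85
max_sweat_rate <- function(age, sex, acclimatized = TRUE,
                           coefficients = sweat_model()) {
  if (any(age < 0)) {
    stop("age must be non-negative", call. = FALSE)
  }
  sex <- match.arg(as.character(sex), c("male", "female"), several.ok = TRUE)
  male <- as.numeric(sex == "male" & age >= coefficients$child_age_cutoff)
  rate <- coefficients$intercept +
    coefficients$male_effect * male +
    coefficients$acclimatization_effect * as.numeric(acclimatized) +
    coefficients$age_slope * age
  pmax(rate, coefficients$floor)
}

#' Metabolic rate by exertion level and body mass
#'
#' Exertion-level anchors at the 70 kg reference individual (125 W rest,
#' 225 W minimal, 600 W moderate, 1280 W heavy) scaled allometrically with
#' mass: `anchor * (mass / 70)^0.75`.
#'
#' @param exertion One of `"rest"`, `"minimal"`, `"moderate"`, `"heavy"`
#'   (vectorized).
#' @param mass Body mass, kg, positive.
#' @param model A [metabolic_model()] object.
#' @return Metabolic rate, W.
#' @export
#' @examples
#' metabolic_rate("rest", 70)   # 125 W
#' metabolic_rate("heavy", 70)  # 1280 W
metabolic_rate <- function(exertion, mass, model = metabolic_model()) {
  if (any(mass <= 0)) {
    stop("mass must be positive", call. = FALSE)
  }
  exertion <- as.character(exertion)
  bad <- !exertion %in% names(model$anchors)
  if (any(bad)) {
    stop("unknown exertion level: ",
         paste(unique(exertion[bad]), collapse = ", "), call. = FALSE)
  }
  unname(model$anchors[exertion]) * (mass / model$reference_mass)^model$mass_exponent
}

#' Build a complete physiological profile for one individual
#'
#' Composes surface area, maximal sweat rate, and metabolic rate into the
#' individual-level inputs of the heat-balance model. `max_sweat_rate` may
#' be supplied explicitly (the population layer passes the discretized bin
#' representative); otherwise it is derived from age, sex, and
#' acclimatization.
#'
#' @param age Age in years.
#' @param sex `"male"` or `"female"`.
#' @param mass Body mass, kg.
#' @param height Height, cm.
#' @param exertion Exertion level, see [metabolic_rate()].
#' @param acclimatized Logical, default `TRUE`.
#' @param models A [manmo_models()] bundle.
#' @param max_sweat_rate Optional explicit maximal sweat rate,
#'   g.min^-1.m^-2, overriding the sweat model.
#' @return An object of class `body_profile`.
#' @export
#' @examples
#' build_body_profile(30, "male", 70, 170, "rest")
build_body_profile <- function(age, sex, mass, height, exertion = "rest",
                               acclimatized = TRUE,
                               models = manmo_models(),
                               max_sweat_rate = NULL) {
  sex <- match.arg(sex, c("male", "female"))
  if (is.null(max_sweat_rate)) {
    max_sweat_rate <- heatstrain::max_sweat_rate(age, sex, acclimatized,
                                                 models$sweat)
  }
  structure(
    list(
      mass = mass,
      height = height,
      surface_area = body_surface_area(mass, height),
      max_sweat_rate = max_sweat_rate,
      metabolic_rate = metabolic_rate(exertion, mass, models$metabolic),
      exertion = exertion,
      sex = sex,
      age = age,
      acclimatized = acclimatized
    ),
    class = "body_profile"
  )
}

#' @export
print.body_profile <- function(x, ...) {
  cat(sprintf(
    "Body profile: %s, age %.0f, %.0f kg, %.0f cm (%s exertion)\n",
    x$sex, x$age, x$mass, x$height, x$exertion
  ))
  cat(sprintf("  surface area   %.3f m^2\n", x$surface_area))
  cat(sprintf("  max sweat rate %.2f g/min/m^2\n", x$max_sweat_rate))
  cat(sprintf("  metabolic rate %.0f W\n", x$metabolic_rate))
  invisible(x)
}
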