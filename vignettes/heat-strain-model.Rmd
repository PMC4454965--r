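---
title: "A population-level heat-strain simulation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A population-level heat-strain simulation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatstrain)
```

## The problem

Heat strain arises when an individual's heat gain — metabolic heat plus
absorbed solar radiation — exceeds what convection, conduction through
clothing, and sweat evaporation can remove. Individual vulnerability varies
strongly with age, sex, body size, and occupation, so a population-level
picture cannot be read off a single representative body. `heatstrain`
scales a steady-state individual heat-budget model (a MANMO-style "man
model") to a national population represented by a modest suite of weighted
*person-types*, and reports, for a given afternoon's weather, the
proportion of each age-sex group whose modelled core temperature would rise
by 2&nbsp;°C or more in one hour.

## The individual heat budget

For one individual under fixed conditions the model computes a steady-state
storage flux

$$S = M + R_{abs} - C - E,$$

with all terms in watts:

* **Metabolic heat** $M$: anchored at a 70&nbsp;kg reference (125&nbsp;W at
  rest, 225&nbsp;W minimal, 600&nbsp;W moderate, 1280&nbsp;W heavy
  exertion) and scaled allometrically as $(m/70)^{0.75}$. The exponent is
  configurable (`metabolic_model(mass_exponent = 1)` gives linear
  scaling); results for the mass effect are sensitive to this choice.
* **Solar gain** $R_{abs} = R_{sol} f_p A \left[p_{cl} r_{cl}
  (1-\alpha_{cl}) + (1-p_{cl})(1-\alpha_{sk})\right]$, where
  $f_p = 0.25$ is the projected-area fraction, $A$ the Du&nbsp;Bois surface
  area $0.007184\,m^{0.425}h^{0.725}$, $p_{cl} = 0.4$ the clothed
  proportion, $r_{cl} = 1.08$ the clothed-area ratio, and both albedos 0.3.
* **Dry exchange** $C$: bare-skin convection
  $h_c A (1-p_{cl}) (T_{sk}-T_a)$ plus conduction through the garment
  $A\,p_{cl}(T_{sk}-T_{cl})/I_{cl}$, with $h_c = \max(8.3\,v^{0.6},\,3.1)$
  W·m⁻²·K⁻¹ and the clothing surface temperature $T_{cl}$ from the linear
  surface balance
  $(T_{sk}-T_{cl})/I_{cl} = h_c (T_{cl}-T_a) - (1-\alpha_{cl}) f_p R_{sol}$,
  solved in closed form (and cross-checked against a numeric root-finder in
  the tests). Insulation defaults to 0.6&nbsp;clo
  ($0.093$&nbsp;m²·K·W⁻¹); the zero-insulation limit returns skin
  temperature rather than dividing by zero.
* **Evaporation** $E = \min(E_{sw}, E_{max})$: the sweat-limited loss
  $E_{sw} = m_{sw} A \lambda \eta / 60$ (maximal sweat rate $m_{sw}$ in
  g·min⁻¹·m⁻², latent heat $\lambda = 2426$&nbsp;J·g⁻¹, efficiency
  $\eta = 0.85$) against the Lewis-relation environmental capacity
  $E_{max} = 16.5\,h_c A\,(p_{sat}(T_{sk}) - \phi\,p_{sat}(T_a))$, floored
  at zero. Saturation pressures use the Tetens form.

Skin temperature is held at 36&nbsp;°C and sweating at its maximum, which
avoids solving for an equilibrium skin temperature and prevents
overestimating evaporative loss. Storage converts to an hourly
core-temperature gain through the tissue heat capacity of
3.5&nbsp;J·g⁻¹·K⁻¹: $\Delta T = 3600\,S / (3500\,m)$, and a gain of
2&nbsp;°C·h⁻¹ or more (inclusive) marks the individual at risk; the
threshold is configurable for sensitivity analysis.

```{r individual}
body <- build_body_profile(age = 30, sex = "male", mass = 70, height = 170,
                           exertion = "moderate")
heat_storage(weather_conditions(43.2, 0.16, 600, 2.5), body)
```

Maximal sweat rate follows a linear model in sex, acclimatization, and age
(7.39 + 2.61·male + 1.16·acclimatized − 0.07·age g·min⁻¹·m⁻²), with boys
under 14 assigned the female rate and a floor of 0.5 preventing
unphysiological non-positive rates in extreme old age. All individuals are
assumed acclimatized by default.

### Formulation choices

The flux correlations above are standard heat-stress-engineering forms,
each independently checkable, with every coefficient exposed in
`heat_balance_config()` so alternative dialects of the man model can be
configured. Two choices deserve note. Long-wave radiation exchange is
omitted — mean radiant temperature is taken equal to air temperature, so
any radiative exchange folds into the convective term; this keeps the
surface balance linear. Respiratory heat loss (the standard
$0.0014\,M(34-T_a) + 0.0173\,M(5.87-\phi\,p_{sat}(T_a))$ form) is
available behind a flag but off by default. The clothed segment's solar
absorption enters both the solar-gain term and, through the raised
clothing-surface temperature, the conduction term; the resulting mild
double counting is accepted as part of this formulation in exchange for
keeping the four flux operations independently defined and testable.

## Scaling to a population

Rather than simulate every individual, the population is collapsed into
person-types: the cross of discretized body bins (10&nbsp;cm height ×
20&nbsp;kg mass blocks, represented by midpoints, including open-ended top
bins), a per-stratum sweat-rate bin (2-unit blocks at the age band's
representative age — the band midpoint, 80 for 75+), and an
occupation-derived distribution over weather exposure (not exposed /
indoors / outdoors) × exertion (rest / minimal / moderate / heavy).
Weights multiply and are conserved within each age-sex stratum, a property
the tests verify to 10⁻⁹ along with exact agreement against brute-force
per-individual enumeration when individuals sit on bin representatives.

Exposure determines the weather an individual actually feels: outdoors
means a 2.5&nbsp;m·s⁻¹ light breeze and the recorded solar flux; indoors
means 0.3&nbsp;m·s⁻¹ (air movement from the body itself), no sun, and —
with no building thermal model — outdoor air temperature. "Not exposed"
individuals can fully modify their environment and contribute zero risk.
For reporting, rest and minimal exertion are merged, giving indoors and
outdoors each three exertion cells plus the collapsed not-exposed cell.

```{r population}
gen <- generator_config(seed = 1)
person_types <- build_person_types(
  discretize_body_distribution(generate_population_table(gen)),
  assign_exposure_exertion(generate_occupation_table(gen), gen$mapping)
)
melbourne <- builtin_city_fixtures()[2, ]
totals <- risk_totals(population_risk(person_types, melbourne))
totals[totals$age_group == "75+", ]
```

## The synthetic population generator

Census-style height-mass custom reports and occupation tables are not
shipped with the package; `generate_population_table()` and
`generate_occupation_table()` produce seeded stand-ins with the structure
the analysis assumes, and are first-class, tested code. Heights are Normal
and mass is log-normal BMI times height squared, with per-age-sex
parameters approximating Australian adult distributions (adult male height
175&nbsp;cm SD&nbsp;7, female 162&nbsp;cm SD&nbsp;6.5, BMI median around
26, lower in children and the oldest band). Each stratum tabulates 400
sampled individuals into whole-centimetre, whole-kilogram pairs — enough to
populate the body bins stably while keeping the default test run fast. The
occupation table uses a ~14-category list collapsed from the usual detailed
classifications, with shares calibrated so that, among those aged 15 and
over, roughly four times more males than females do moderate-or-heavy
exertion work outdoors (verified within 5% at generation time; an
infeasible target raises a configuration error). Children's strata contain
schooling, preschool, and sex-symmetric outdoor play, never heavy work —
for that reason the 4:1 calibration is evaluated over adult strata only.
`generate_weather_series()` adds a seeded sinusoid-plus-noise summer
series with configurable heatwave spikes for time-series demonstrations.

What the generator does *not* emulate: real census proportions (only
distributional shape), within-stratum correlation of occupation with body
size, regional variation, and household air-conditioning structure beyond
the flat "protected" share. Passing tests therefore demonstrate the
machinery and the model's comparative patterns — not numerical estimates
for any real population.

## Behavior worth knowing about

* **Monotonicity.** Storage (and hence every stratum's risk) is
  non-decreasing in air temperature, humidity, solar radiation, and
  metabolic rate, and non-increasing in maximal sweat rate while
  sweat-limited. The tests check this over a 20×10×5 weather grid.
* **A weather-independent risk floor.** With skin fixed at 36&nbsp;°C and
  sweating maximal, an individual whose metabolic load exceeds their
  maximum dissipation (sweat-capped evaporation plus the dry-exchange
  ceiling) is at risk at *any* air temperature: outdoor heavy work, and
  indoor moderate exertion for low-sweat strata such as women over 75,
  retain residual risk even on a 10&nbsp;°C day. This is a structural
  consequence of the steady-state formulation, consistent with its
  comparative purpose, but it means absolute cold-weather proportions
  should not be over-read.
* **Threshold sensitivity.** Across risk thresholds of 1.5, 2.0, and
  2.5&nbsp;°C·h⁻¹ on the hottest fixture day, per-stratum risk shrinks
  pointwise as the threshold tightens and the stratum ranking stays
  strongly correlated (Spearman ≥ 0.84 for every pair in the default
  configuration). One genuine movement exists: the 45–54 male stratum,
  whose outdoor risk is marginal, falls several ranks at the tightest
  threshold while female sweat-limited risk persists.
* **Numerical choices.** The clothing-surface solve is exact (linear);
  budget closure holds to 10⁻⁹&nbsp;W by construction and is verified on
  10,000 random inputs; bin representatives are arithmetic midpoints
  (unbiased under within-bin uniformity); the risk comparison is
  inclusive (≥). Degenerate inputs — zero insulation, saturated air, zero
  solar — are handled as limits, not errors.
* **Problem sizes.** The default generator yields roughly 1,700
  person-types across 18 strata; a four-city run evaluates in well under a
  second, and the full test suite in a few seconds.

## Limitations

The model is steady-state: no transient core-temperature dynamics, no
thermoregulatory feedback, one clothing layer, one body segment. Daily
solar radiation is treated as the 3&nbsp;p.m. instantaneous flux (a
configurable scale factor is provided). Indoor temperature equals outdoor
temperature. Occupation-based exposure ignores recreational heat exposure
and any behavioral adaptation on hot days, so outputs are upper bounds of
the "no behavior change" kind. Percent body fat, cardiovascular
comorbidity, and acclimatization dynamics are not modelled.
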