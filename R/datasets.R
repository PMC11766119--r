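#' Construct a rate dataset
#'
#' The common container consumed by [fit_model()]: one row per
#' observation with a temperature, a response, and a unit weight
#' (reserved; the fits are ordinary least squares). The response kind
#' and stage ride along as attributes so that comparisons can refuse to
#' rank fits made on different data.
#'
#' @param temperature Numeric vector of temperatures (degrees Celsius).
#' @param response Numeric response (day^-1 rates, proportions, or eggs).
#' @param response_kind One of `"development_rate"`,
#'   `"mortality_proportion"`, `"inverse_longevity"`, `"total_eggs"`.
#' @param stage Stage or sex label the data describe.
#' @return A `rate_dataset` (data frame with attributes).
#' @export
rate_dataset <- function(temperature, response,
                         response_kind = c("development_rate",
                                           "mortality_proportion",
                                           "inverse_longevity",
                                           "total_eggs"),
                         stage = NA_character_) {
  response_kind <- match.arg(response_kind)
  if (!length(temperature) || length(temperature) != length(response))
    stop("temperature and response must be equal-length, non-empty",
         call. = FALSE)
  if (any(!is.finite(temperature)) || any(!is.finite(response)))
    stop("rate dataset values must be finite", call. = FALSE)
  if (response_kind == "mortality_proportion" &&
      (any(response < 0) || any(response > 1)))
    stop("mortality proportions must lie in [0, 1]", call. = FALSE)
  ds <- data.frame(temperature = temperature, response = response,
                   weight = 1)
  attr(ds, "response_kind") <- response_kind
  attr(ds, "stage") <- stage
  class(ds) <- c("rate_dataset", "data.frame")
  ds
}

#' Development-rate dataset for one stage
#'
#' One point per individual that completed the stage (reciprocal
#' duration), across all temperatures. Individual-level points — not
#' per-temperature means — so the fit degrees of freedom reflect the
#' full cohort.
#'
#' @param durations Duration data frame from [extract_stage_durations()].
#' @param stage Preimaginal stage name.
#' @return A `rate_dataset` of kind `"development_rate"`.
#' @export
build_development_dataset <- function(durations, stage) {
  rates <- durations_to_rates(durations)
  rates <- rates[rates$stage == stage, , drop = FALSE]
  if (!nrow(rates))
    stop("no completed durations for stage ", stage, call. = FALSE)
  rate_dataset(rates$temperature_C, rates$rate_per_day,
               "development_rate", stage)
}

#' Mortality dataset for one stage
#'
#' One point per temperature, response `1 - relative survival`
#' recomputed from the life-table counts.
#'
#' @param life_table Life-table data frame from [stage_life_table()].
#' @param stage Preimaginal stage name.
#' @return A `rate_dataset` of kind `"mortality_proportion"`.
#' @export
build_mortality_dataset <- function(life_table, stage) {
  rows <- life_table[life_table$stage == stage & life_table$n_entered > 0, ,
                     drop = FALSE]
  if (!nrow(rows)) stop("no life-table rows for stage ", stage, call. = FALSE)
  rate_dataset(rows$temperature_C, relative_mortality(rows),
               "mortality_proportion", stage)
}

#' Inverse-longevity dataset for one sex
#'
#' One point per adult individual, response `1/longevity` (day^-1), for
#' the requested sex.
#'
#' @param longevities Individual-level data frame from
#'   [adult_longevities()].
#' @param sex `"male"` or `"female"`.
#' @return A `rate_dataset` of kind `"inverse_longevity"`.
#' @export
build_longevity_dataset <- function(longevities, sex = c("male", "female")) {
  sex <- match.arg(sex)
  rows <- longevities[longevities$sex == sex, , drop = FALSE]
  if (!nrow(rows)) stop("no adults of sex ", sex, call. = FALSE)
  if (any(rows$longevity_days <= 0))
    stop("longevity must be positive to invert", call. = FALSE)
  rate_dataset(rows$temperature_C, 1 / rows$longevity_days,
               "inverse_longevity", paste0("adult_", sex))
}

#' Total-egg dataset from a fecundity summary
#'
#' One point per temperature: the mean lifetime egg total per female.
#'
#' @param fec_summary Data frame from [fecundity_summary()] (or the
#'   bundled study table, see [suzukii_fecundity_table()]).
#' @return A `rate_dataset` of kind `"total_eggs"`.
#' @export
build_fecundity_dataset <- function(fec_summary) {
  col <- if ("mean_total_eggs" %in% names(fec_summary)) "mean_total_eggs"
         else "total_eggs_mean"
  rate_dataset(fec_summary$temperature_C, fec_summary[[col]],
               "total_eggs", "adult_female")
}

#' Bundled Drosophila suzukii study tables
#'
#' The published constant-temperature life-table summaries for the
#' Apulian D. suzukii cohorts, shipped as plain-text fixtures:
#' preimaginal stage statistics with survivor counts (50-egg cohorts at
#' 14 temperatures, 6-33 C), adult longevity by sex, and per-female
#' pre-oviposition and lifetime egg production (10 couples per
#' temperature). Entrant counts chain across stages (a stage's entrants
#' are the previous stage's survivors); survival is recomputed from the
#' counts, which for a couple of printed cells differs from the rounded
#' published proportion. These tables are both reference data and the
#' default parameterisation of the synthetic-cohort generator.
#'
#' @return Data frame matching the corresponding CSV under
#'   `inst/extdata/`.
#' @export
suzukii_stage_table <- function() {
  utils::read.csv(system.file("extdata", "suzukii_stage_table.csv",
                              package = "lifetherm"))
}

#' @rdname suzukii_stage_table
#' @export
suzukii_adult_table <- function() {
  utils::read.csv(system.file("extdata", "suzukii_adult_table.csv",
                              package = "lifetherm"))
}

#' @rdname suzukii_stage_table
#' @export
suzukii_fecundity_table <- function() {
  utils::read.csv(system.file("extdata", "suzukii_fecundity_table.csv",
                              package = "lifetherm"))
}
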