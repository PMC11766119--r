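#' Stage vocabulary
#'
#' The seven observable life stages, in developmental order for the
#' preimaginal part (egg < L1 < L2 < L3 < pupa); the two adult stages are
#' terminal.
#' @return Character vector of stage names.
#' @export
stage_levels <- function() {
  c("egg", "L1", "L2", "L3", "pupa", "adult_male", "adult_female")
}

.PREIMAGINAL <- c("egg", "L1", "L2", "L3", "pupa")
.ADULTS <- c("adult_male", "adult_female")

.stage_rank <- function(stage) {
  # adults share one rank: the record may move pupa -> adult_male OR
  # adult_female, but never between the two adult stages
  r <- match(stage, stage_levels())
  r[r == 7L] <- 6L
  r
}

#' Extract per-stage durations from individual inspection records
#'
#' Realizes stage-development times from raw inspection histories. For
#' each stage an individual entered, the duration is the difference
#' between the first inspection time at which the *next* stage was
#' observed and the first time at which *this* stage was observed
#' (first-observation convention: durations live on the inspection grid,
#' which is how the source tables report them). An individual that died
#' in a stage contributes an incomplete duration (time from stage entry
#' to the death observation) with `completed = FALSE`; incomplete
#' durations are excluded from duration statistics but counted in
#' survival denominators.
#'
#' Individuals whose history is malformed (non-increasing times, a
#' skipped stage such as egg followed directly by L2, observations after
#' death) are quarantined: they contribute no durations and are listed
#' in the `"flagged"` attribute with a reason, mirroring
#' [validate_records()].
#'
#' @param records Long data frame of inspection records with columns
#'   `individual_id`, `temperature_C`, `time_days`, `stage`, `alive`
#'   (logical or 0/1).
#' @param midpoint Apply a half-interval midpoint correction to each
#'   transition (sensitivity analysis toggle; default `FALSE`, the
#'   first-observation convention).
#' @return Data frame with columns `individual_id`, `temperature_C`,
#'   `stage`, `duration_days`, `completed`, plus attribute `"flagged"`
#'   (data frame `individual_id`, `reason` of quarantined individuals).
#' @examples
#' rec <- data.frame(individual_id = "a", temperature_C = 26,
#'                   time_days = c(0, 1, 2), stage = c("egg", "L1", "L2"),
#'                   alive = TRUE)
#' extract_stage_durations(rec)
#' @export
extract_stage_durations <- function(records, midpoint = FALSE) {
  records <- .normalize_records(records)
  out <- vector("list", 0L)
  flagged <- list()
  for (sub in split(records, records$individual_id)) {
    # history is checked in recorded order: unordered timestamps are a
    # data problem, not something to fix silently
    bad <- .history_problem(sub)
    if (!is.na(bad)) {
      flagged[[length(flagged) + 1L]] <-
        data.frame(individual_id = sub$individual_id[1], reason = bad)
      next
    }
    out[[length(out) + 1L]] <- .one_history_durations(sub, midpoint)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(individual_id = character(), temperature_C = numeric(),
               stage = character(), duration_days = numeric(),
               completed = logical())
  rownames(res) <- NULL
  attr(res, "flagged") <- if (length(flagged)) do.call(rbind, flagged) else
    data.frame(individual_id = character(), reason = character())
  res
}

.normalize_records <- function(records) {
  need <- c("individual_id", "temperature_C", "time_days", "stage", "alive")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  records$alive <- as.logical(records$alive)
  records$stage <- as.character(records$stage)
  records
}

.history_problem <- function(sub) {
  if (any(!sub$stage %in% stage_levels())) return("unknown stage label")
  if (any(diff(sub$time_days) <= 0)) return("non-monotone time")
  r <- .stage_rank(sub$stage)
  if (any(diff(r) < 0)) return("stage order regression")
  if (any(diff(r) > 1)) return("skipped stage")
  if (sum(sub$stage %in% .ADULTS[1]) && sum(sub$stage %in% .ADULTS[2]))
    return("both adult stages observed")
  dead <- which(!sub$alive)
  if (length(dead) && any(sub$alive[seq_len(nrow(sub)) > min(dead)]))
    return("alive observation after death")
  NA_character_
}

.one_history_durations <- function(sub, midpoint = FALSE) {
  stages <- unique(sub$stage)
  first_t <- vapply(stages, function(s) min(sub$time_days[sub$stage == s]),
                    numeric(1))
  death_t <- if (any(!sub$alive)) min(sub$time_days[!sub$alive]) else NA_real_
  # Midpoint correction only shifts durations where one endpoint is known
  # exactly: the entry of the first stage (egg deposition at time 0). All
  # interior transitions carry the same half-interval bias on both
  # endpoints, which cancels in the difference.
  half <- if (midpoint && nrow(sub) > 1)
    stats::median(diff(sub$time_days)) / 2 else 0
  t0 <- min(sub$time_days)
  pre <- intersect(.PREIMAGINAL, stages)
  rows <- lapply(seq_along(pre), function(i) {
    s <- pre[i]
    nxt_rank <- .stage_rank(s) + 1L
    nxt <- stages[.stage_rank(stages) == nxt_rank]
    if (length(nxt)) {
      dur <- first_t[[nxt[1]]] - first_t[[s]] -
        if (first_t[[s]] == t0) half else 0
      data.frame(individual_id = sub$individual_id[1],
                 temperature_C = sub$temperature_C[1], stage = s,
                 duration_days = dur, completed = TRUE)
    } else {
      dur <- if (!is.na(death_t)) death_t - first_t[[s]] else NA_real_
      data.frame(individual_id = sub$individual_id[1],
                 temperature_C = sub$temperature_C[1], stage = s,
                 duration_days = dur, completed = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Summary statistics for one stage at one temperature
#'
#' Builds one life-table row: duration statistics over *completed*
#' durations (sample mean and SD with the n-1 denominator, median, mode
#' as the most frequent grid value, adjusted Fisher-Pearson skewness,
#' bias-adjusted excess kurtosis) and relative survival as the fraction
#' of entrants that completed the stage. Skewness needs at least 3
#' completed durations and kurtosis at least 4; the mode is missing when
#' every duration is unique. With zero completions the duration fields
#' are all missing but survival (0) is still reported.
#'
#' @param durations Duration data frame as produced by
#'   [extract_stage_durations()].
#' @param stage Stage name to summarize.
#' @param temperature Rearing temperature (degrees Celsius).
#' @return One-row data frame: `stage`, `temperature_C`, `n_entered`,
#'   `n_survived`, `mean_days`, `sd_days`, `mode_days`, `median_days`,
#'   `kurtosis`, `skewness`, `relative_survival`.
#' @export
summarize_stage <- function(durations, stage, temperature) {
  sel <- durations$stage == stage &
    abs(durations$temperature_C - temperature) < 1e-9
  d <- durations[sel, , drop = FALSE]
  if (!nrow(d)) stop("no individuals entered ", stage, " at ",
                     temperature, " C", call. = FALSE)
  n_entered <- nrow(d)
  x <- d$duration_days[d$completed]
  n <- length(x)
  stats_row <- if (n > 0) {
    data.frame(mean_days = mean(x),
               sd_days = if (n > 1) stats::sd(x) else NA_real_,
               mode_days = .grid_mode(x),
               median_days = stats::median(x),
               kurtosis = if (n >= 4) e1071::kurtosis(x, type = 2) else NA_real_,
               skewness = if (n >= 3) e1071::skewness(x, type = 2) else NA_real_)
  } else {
    data.frame(mean_days = NA_real_, sd_days = NA_real_, mode_days = NA_real_,
               median_days = NA_real_, kurtosis = NA_real_,
               skewness = NA_real_)
  }
  cbind(data.frame(stage = stage, temperature_C = temperature,
                   n_entered = n_entered, n_survived = n),
        stats_row,
        data.frame(relative_survival = n / n_entered))
}

# Most frequent value; ties -> smallest; all unique -> NA (the "--"
# entries of the published tables).
.grid_mode <- function(x) {
  tab <- table(x)
  if (max(tab) <= 1L) return(NA_real_)
  as.numeric(names(tab)[which(tab == max(tab))[1]])
}

#' Full preimaginal life table
#'
#' Applies [summarize_stage()] to every stage-temperature combination
#' with at least one entrant, in stage order.
#'
#' @inheritParams extract_stage_durations
#' @param durations Optionally a precomputed duration data frame; when
#'   `NULL` it is extracted from `records`.
#' @return Data frame of life-table rows (one per stage x temperature).
#' @export
stage_life_table <- function(records, durations = NULL, midpoint = FALSE) {
  if (is.null(durations)) durations <- extract_stage_durations(records, midpoint)
  combos <- unique(durations[c("stage", "temperature_C")])
  combos <- combos[order(match(combos$stage, .PREIMAGINAL),
                         combos$temperature_C), , drop = FALSE]
  rows <- Map(function(s, temp) summarize_stage(durations, s, temp),
              combos$stage, combos$temperature_C)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Relative mortality from a life-table row
#'
#' The complement of relative survival, `M = 1 - n_survived/n_entered`,
#' recomputed from the counts (not the rounded displayed proportion).
#'
#' @param row Life-table row(s) with `n_entered` and `n_survived`
#'   columns (vectorised over rows).
#' @return Numeric vector of mortality proportions in [0, 1].
#' @export
relative_mortality <- function(row) {
  if (any(row$n_entered <= 0))
    stop("n_entered must be positive", call. = FALSE)
  1 - row$n_survived / row$n_entered
}

#' Convert completed stage durations to development rates
#'
#' One development-rate point per individual, `rate = 1/duration`
#' (day^-1), keeping the temperature and stage tags. Only completed
#' durations are convertible.
#'
#' @param durations Duration data frame from [extract_stage_durations()].
#' @return Data frame `individual_id`, `temperature_C`, `stage`,
#'   `rate_per_day`.
#' @export
durations_to_rates <- function(durations) {
  d <- durations[durations$completed, , drop = FALSE]
  if (any(d$duration_days <= 0))
    stop("completed durations must be positive to invert", call. = FALSE)
  data.frame(individual_id = d$individual_id,
             temperature_C = d$temperature_C,
             stage = d$stage,
             rate_per_day = 1 / d$duration_days,
             row.names = NULL)
}

#' Individual adult longevities
#'
#' Longevity of each adult as death time minus first adult observation
#' (emergence on the inspection grid). Adults with no recorded death are
#' excluded with a warning.
#'
#' @inheritParams extract_stage_durations
#' @return Data frame `individual_id`, `temperature_C`, `sex`
#'   (`"male"`/`"female"`), `longevity_days`.
#' @export
adult_longevities <- function(records) {
  records <- .normalize_records(records)
  rows <- list(); dropped <- character()
  for (sub in split(records, records$individual_id)) {
    sub <- sub[order(sub$time_days), , drop = FALSE]
    ad <- sub$stage %in% .ADULTS
    if (!any(ad)) next
    emergence <- min(sub$time_days[ad])
    if (all(sub$alive)) { dropped <- c(dropped, sub$individual_id[1]); next }
    death <- min(sub$time_days[!sub$alive])
    rows[[length(rows) + 1L]] <- data.frame(
      individual_id = sub$individual_id[1],
      temperature_C = sub$temperature_C[1],
      sex = if (sub$stage[which(ad)[1]] == "adult_male") "male" else "female",
      longevity_days = death - emergence)
  }
  if (length(dropped))
    warning("excluded ", length(dropped),
            " adult(s) with no death observation: ",
            paste(utils::head(dropped, 5), collapse = ", "))
  if (!length(rows))
    return(data.frame(individual_id = character(), temperature_C = numeric(),
                      sex = character(), longevity_days = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Adult longevity life table
#'
#' Per-sex, per-temperature longevity summaries with the same statistics
#' as the preimaginal table; survival fields are absent because there is
#' no later stage to survive to.
#'
#' @inheritParams extract_stage_durations
#' @return Data frame `sex`, `temperature_C`, `n`, `mean_days`,
#'   `sd_days`, `mode_days`, `median_days`, `kurtosis`, `skewness`.
#' @export
adult_longevity_table <- function(records) {
  lon <- adult_longevities(records)
  combos <- unique(lon[c("sex", "temperature_C")])
  combos <- combos[order(match(combos$sex, c("male", "female")),
                         combos$temperature_C), , drop = FALSE]
  rows <- Map(function(sx, temp) {
    x <- lon$longevity_days[lon$sex == sx &
                              abs(lon$temperature_C - temp) < 1e-9]
    n <- length(x)
    data.frame(sex = sx, temperature_C = temp, n = n,
               mean_days = mean(x),
               sd_days = if (n > 1) stats::sd(x) else NA_real_,
               mode_days = .grid_mode(x),
               median_days = stats::median(x),
               kurtosis = if (n >= 4) e1071::kurtosis(x, type = 2) else NA_real_,
               skewness = if (n >= 3) e1071::skewness(x, type = 2) else NA_real_)
  }, combos$sex, combos$temperature_C)
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sex = character(), temperature_C = numeric(), n = integer(),
               mean_days = numeric(), sd_days = numeric(),
               mode_days = numeric(), median_days = numeric(),
               kurtosis = numeric(), skewness = numeric())
  rownames(out) <- NULL
  out
}

#' Pre-oviposition and total egg production summaries
#'
#' Per-temperature means and standard errors (SD/sqrt(n)) across females
#' of (i) the pre-oviposition period, the day index of the first nonzero
#' daily egg count with the pairing day as time zero, and (ii) lifetime
#' total eggs. Females that never laid are excluded from the
#' pre-oviposition mean (with a message) but contribute a zero total.
#'
#' @param fecundity Data frame of per-couple daily counts with columns
#'   `female_id`, `temperature_C`, `day` (integer index starting at 1),
#'   `eggs` (non-negative integer).
#' @return Data frame `temperature_C`, `n_females`,
#'   `mean_preoviposition`, `se_preoviposition`, `mean_total_eggs`,
#'   `se_total_eggs`.
#' @export
fecundity_summary <- function(fecundity) {
  need <- c("female_id", "temperature_C", "day", "eggs")
  miss <- setdiff(need, names(fecundity))
  if (length(miss))
    stop("fecundity records missing columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  if (any(fecundity$eggs < 0)) stop("egg counts must be >= 0", call. = FALSE)
  if (any(fecundity$day < 1)) stop("day index starts at 1", call. = FALSE)
  se <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  rows <- lapply(split(fecundity, fecundity$temperature_C), function(d) {
    per <- lapply(split(d, d$female_id), function(f) {
      f <- f[order(f$day), , drop = FALSE]
      laid <- f$day[f$eggs > 0]
      data.frame(preovip = if (length(laid)) min(laid) else NA_real_,
                 total = sum(f$eggs))
    })
    per <- do.call(rbind, per)
    if (anyNA(per$preovip))
      message(sum(is.na(per$preovip)), " female(s) at ",
              d$temperature_C[1],
              " C laid no eggs; excluded from pre-oviposition mean")
    po <- per$preovip[!is.na(per$preovip)]
    data.frame(temperature_C = d$temperature_C[1],
               n_females = nrow(per),
               mean_preoviposition = if (length(po)) mean(po) else NA_real_,
               se_preoviposition = if (length(po)) se(po) else NA_real_,
               mean_total_eggs = mean(per$total),
               se_total_eggs = se(per$total))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$temperature_C), , drop = FALSE]
  rownames(out) <- NULL
  out
}
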