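#' Configuration of the synthetic cohort generator
#'
#' Encodes the constant-temperature rearing design the generator
#' emulates: cohorts of 50 individually followed eggs at each of 14
#' temperatures between 6 and 33 C, inspected on a temperature-dependent
#' schedule (every 24 h at 6-13 C, 8 h at 18-20 C, 6 h at 24-27 C, 4 h
#' at 28-29 C, 2 h at 31-33 C), with 10 couples per temperature for the
#' egg-production trial. Stage survival probabilities and duration
#' means/SDs default to the bundled study tables
#' ([suzukii_stage_table()] and friends), so the generator's defaults
#' *are* the study conditions.
#'
#' @param temperatures Rearing temperatures (degrees Celsius).
#' @param cohort_size Eggs per cohort.
#' @param n_couples Couples in the egg-production trial.
#' @param seed Integer seed; all draws derive from it.
#' @param inspection_hours Named map temperature -> inspection interval
#'   in hours.
#' @param stage_table,adult_table,fecundity_table Parameter tables in the
#'   layout of the bundled fixtures.
#' @param duration_dist `"lognormal"` (default; positive support and the
#'   mild right skew seen in the study tables) or `"gamma"`.
#' @param sex_ratio Probability an individual completing the pupal stage
#'   emerges male.
#' @return A `generator_config` list.
#' @export
generator_config <- function(temperatures = c(6, 9, 13, 18, 20, 24, 25, 26,
                                              27, 28, 29, 31, 32, 33),
                             cohort_size = 50,
                             n_couples = 10,
                             seed = 1,
                             inspection_hours = default_inspection_hours(),
                             stage_table = suzukii_stage_table(),
                             adult_table = suzukii_adult_table(),
                             fecundity_table = suzukii_fecundity_table(),
                             duration_dist = c("lognormal", "gamma"),
                             sex_ratio = 0.5) {
  duration_dist <- match.arg(duration_dist)
  stopifnot(cohort_size >= 1, n_couples >= 1,
            sex_ratio >= 0, sex_ratio <= 1)
  missing_int <- setdiff(as.character(temperatures), names(inspection_hours))
  if (length(missing_int))
    stop("no inspection interval for temperature(s): ",
         paste(missing_int, collapse = ", "), call. = FALSE)
  structure(list(temperatures = temperatures, cohort_size = cohort_size,
                 n_couples = n_couples, seed = as.integer(seed),
                 inspection_hours = inspection_hours,
                 stage_table = stage_table, adult_table = adult_table,
                 fecundity_table = fecundity_table,
                 duration_dist = duration_dist, sex_ratio = sex_ratio),
            class = "generator_config")
}

#' Default inspection intervals by temperature
#' @return Named numeric vector, hours between inspections keyed by
#'   temperature.
#' @export
default_inspection_hours <- function() {
  c(`6` = 24, `9` = 24, `13` = 24, `18` = 8, `20` = 8,
    `24` = 6, `25` = 6, `26` = 6, `27` = 6, `28` = 4, `29` = 4,
    `31` = 2, `32` = 2, `33` = 2)
}

# Deterministic per-(seed, temperature, stream) RNG seed below 2^31.
.stream_seed <- function(cfg, temperature, stream = 0L) {
  idx <- match(temperature, cfg$temperatures)
  if (is.na(idx)) idx <- (round(temperature * 8) %% 997L) + 15L
  (abs(cfg$seed) %% 99991L) * 20011L + idx * 101L + stream
}

# Survival probability + duration (mean, sd) for a stage at a
# temperature; duration falls back to the nearest temperature with data
# for the stage (needed to place a death time inside a stage no one
# completed).
.stage_param <- function(tab, stage, temperature) {
  rows <- tab[tab$stage == stage, , drop = FALSE]
  r <- rows[abs(rows$temperature_C - temperature) < 1e-9, , drop = FALSE]
  if (!nrow(r)) stop("stage table has no row for ", stage, " at ",
                     temperature, " C", call. = FALSE)
  p <- if (r$n_entered > 0) r$n_survived / r$n_entered else 0
  m <- r$mean_days; s <- r$sd_days
  if (is.na(m)) {
    have <- rows[!is.na(rows$mean_days), , drop = FALSE]
    if (nrow(have)) {
      j <- which.min(abs(have$temperature_C - temperature))
      m <- have$mean_days[j]; s <- have$sd_days[j]
    }
  }
  list(p = p, mean = m, sd = if (is.na(s)) 0 else s)
}

.adult_param <- function(tab, sex, temperature) {
  rows <- tab[tab$sex == sex, , drop = FALSE]
  r <- rows[abs(rows$temperature_C - temperature) < 1e-9, , drop = FALSE]
  if (nrow(r) && !is.na(r$mean_days))
    return(list(mean = r$mean_days, sd = r$sd_days))
  have <- rows[!is.na(rows$mean_days), , drop = FALSE]
  j <- which.min(abs(have$temperature_C - temperature))
  list(mean = have$mean_days[j], sd = have$sd_days[j])
}

.draw_duration <- function(n, m, s, dist) {
  if (is.na(m)) return(rep(NA_real_, n))
  if (s <= 0) return(rep(m, n))
  if (dist == "lognormal") {
    sdlog <- sqrt(log(1 + (s / m)^2))
    stats::rlnorm(n, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  } else {
    stats::rgamma(n, shape = (m / s)^2, scale = s^2 / m)
  }
}

#' Generate one synthetic cohort at a constant temperature
#'
#' Simulates the latent life history of `cohort_size` individuals: each
#' stage is survived with the configured probability; survivors draw a
#' stage duration from the configured distribution, while deaths occur
#' at a uniform fraction of the drawn duration (the study reports no
#' within-stage death-time model; this is a declared stand-in). Sex is
#' assigned at pupal completion; adults draw a lognormal longevity.
#' Continuous histories are then discretized onto the temperature's
#' inspection grid: the record shows, at every inspection time, the
#' stage the individual is in and whether it is alive, ending with the
#' death observation — exactly the structure of the rearing datasheets.
#'
#' @param cfg A [generator_config()].
#' @param temperature One of `cfg$temperatures`.
#' @return List with `records` (long inspection data frame, see
#'   [extract_stage_durations()]) and `truth` (per-individual latent
#'   history: stage entry times, death time, sex).
#' @export
generate_cohort <- function(cfg, temperature) {
  stopifnot(inherits(cfg, "generator_config"))
  if (!temperature %in% cfg$temperatures)
    stop("temperature ", temperature, " not in the configuration",
         call. = FALSE)
  set.seed(.stream_seed(cfg, temperature, 0L))
  n <- cfg$cohort_size
  stages <- .PREIMAGINAL
  entry <- matrix(NA_real_, n, length(stages) + 1L,
                  dimnames = list(NULL, c(stages, "adult")))
  entry[, "egg"] <- 0
  death <- rep(NA_real_, n)
  sex <- rep(NA_character_, n)
  alive_in <- rep(TRUE, n)  # still developing at current stage entry
  for (si in seq_along(stages)) {
    idx <- which(alive_in & !is.na(entry[, si]))
    if (!length(idx)) break
    sp <- .stage_param(cfg$stage_table, stages[si], temperature)
    surv <- stats::runif(length(idx)) < sp$p
    dur <- .draw_duration(length(idx), sp$mean, sp$sd, cfg$duration_dist)
    dur[is.na(dur)] <- 1  # stage with no duration data anywhere: nominal day
    t0 <- entry[idx, si]
    completes <- idx[surv]
    dies <- idx[!surv]
    entry[completes, si + 1L] <- t0[surv] + dur[surv]
    death[dies] <- t0[!surv] + stats::runif(length(dies)) * dur[!surv]
    alive_in[dies] <- FALSE
  }
  emerged <- which(!is.na(entry[, "adult"]))
  if (length(emerged)) {
    sex[emerged] <- ifelse(stats::runif(length(emerged)) < cfg$sex_ratio,
                           "male", "female")
    for (sx in c("male", "female")) {
      ii <- emerged[sex[emerged] == sx]
      if (!length(ii)) next
      ap <- .adult_param(cfg$adult_table, sx, temperature)
      death[ii] <- entry[ii, "adult"] +
        .draw_duration(length(ii), ap$mean, ap$sd, cfg$duration_dist)
    }
  }
  truth <- data.frame(individual_id = sprintf("T%g_%03d", temperature,
                                              seq_len(n)),
                      temperature_C = temperature, sex = sex,
                      entry, death_time = death, check.names = FALSE)
  names(truth)[4:9] <- paste0("entry_", c(stages, "adult"))
  records <- .discretize_histories(truth, cfg, temperature)
  list(records = records, truth = truth)
}

.discretize_histories <- function(truth, cfg, temperature) {
  h <- cfg$inspection_hours[[as.character(temperature)]] / 24
  entry_cols <- paste0("entry_", c(.PREIMAGINAL, "adult"))
  out <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    entries <- as.numeric(truth[i, entry_cols])
    death <- truth$death_time[i]
    n_obs <- ceiling(death / h - 1e-9)
    times <- h * (0:n_obs)
    stage_idx <- findInterval(times, entries[!is.na(entries)] -
                                1e-12)  # entry at t counts at inspection t
    labels <- c(.PREIMAGINAL,
                if (!is.na(truth$sex[i]) && truth$sex[i] == "male")
                  "adult_male" else "adult_female")[seq_len(
                    sum(!is.na(entries)))]
    stage_obs <- labels[pmax(stage_idx, 1L)]
    alive <- times < death
    # stage recorded at the death observation is the stage at death
    out[[i]] <- data.frame(individual_id = truth$individual_id[i],
                           temperature_C = temperature,
                           time_days = times, stage = stage_obs,
                           alive = alive)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate synthetic cohorts at every configured temperature
#'
#' @param cfg A [generator_config()].
#' @return List with combined `records` and `truth` data frames.
#' @export
generate_cohorts <- function(cfg) {
  parts <- lapply(cfg$temperatures, function(temp) generate_cohort(cfg, temp))
  list(records = do.call(rbind, lapply(parts, `[[`, "records")),
       truth = do.call(rbind, lapply(parts, `[[`, "truth")))
}

#' Generate per-couple daily egg counts at a constant temperature
#'
#' Emulates the egg-production trial: each of `n_couples` females draws
#' a longevity (from the adult-female table), a pre-oviposition delay
#' (rounded Gamma with the configured mean for that temperature), and a
#' lifetime egg target (Gamma across females, with the between-female
#' dispersion implied by the published standard errors at n = 10);
#' daily counts are Poisson around a flat intensity over the oviposition
#' days and truncated at the female's death. Day 1 is the first day
#' after pairing.
#'
#' @inheritParams generate_cohort
#' @return Data frame `female_id`, `temperature_C`, `day`, `eggs`;
#'   empty (with a warning) at temperatures where no adult develops.
#' @export
generate_fecundity <- function(cfg, temperature) {
  stopifnot(inherits(cfg, "generator_config"))
  ft <- cfg$fecundity_table
  row <- ft[abs(ft$temperature_C - temperature) < 1e-9, , drop = FALSE]
  if (!nrow(row) || is.na(row$total_eggs_mean)) {
    warning("temperature ", temperature,
            " C does not permit adult development; no fecundity records")
    return(data.frame(female_id = character(), temperature_C = numeric(),
                      day = integer(), eggs = integer()))
  }
  set.seed(.stream_seed(cfg, temperature, 50021L))
  ap <- .adult_param(cfg$adult_table, "female", temperature)
  out <- vector("list", cfg$n_couples)
  for (i in seq_len(cfg$n_couples)) {
    longevity <- .draw_duration(1, ap$mean, ap$sd, cfg$duration_dist)
    n_days <- max(1L, floor(longevity))
    preovip <- max(1L, round(stats::rgamma(1, shape = 4,
                                           scale = row$preovip_mean_days / 4)))
    cv <- if (row$total_eggs_mean > 0)
      row$total_eggs_se * sqrt(10) / row$total_eggs_mean else 0
    target <- if (cv > 0)
      stats::rgamma(1, shape = 1 / cv^2,
                    scale = row$total_eggs_mean * cv^2)
    else row$total_eggs_mean
    eggs <- integer(n_days)
    ovip <- seq_len(n_days) >= preovip
    if (any(ovip))
      eggs[ovip] <- stats::rpois(sum(ovip), target / sum(ovip))
    out[[i]] <- data.frame(female_id = sprintf("F%g_%02d", temperature, i),
                           temperature_C = temperature,
                           day = seq_len(n_days), eggs = eggs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
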