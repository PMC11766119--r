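test_that("durations come from first-observation differences", {
  d <- extract_stage_durations(simple_history())
  expect_equal(d$stage, c("egg", "L1", "L2"))
  expect_equal(d$duration_days[1:2], c(1, 1))
  expect_true(all(d$completed[1:2]))
  expect_false(d$completed[3])  # L2 entered, neither completed nor died
})

test_that("death in a stage yields an incomplete duration", {
  rec <- simple_history(times = c(0, 1, 1.5),
                        stages = c("egg", "egg", "egg"),
                        alive = c(TRUE, TRUE, FALSE))
  d <- extract_stage_durations(rec)
  expect_equal(nrow(d), 1)
  expect_false(d$completed)
  expect_equal(d$duration_days, 1.5)
})

test_that("malformed histories are quarantined with a reason, not dropped silently", {
  skipped <- simple_history(id = "bad1",
                            stages = c("egg", "L2", "L3"))
  backwards <- simple_history(id = "bad2", times = c(0, 2, 1))
  zombie <- simple_history(id = "bad3", alive = c(TRUE, FALSE, TRUE))
  good <- simple_history(id = "ok")
  d <- extract_stage_durations(rbind(skipped, backwards, zombie, good))
  flagged <- attr(d, "flagged")
  expect_setequal(flagged$individual_id, c("bad1", "bad2", "bad3"))
  expect_true("skipped stage" %in% flagged$reason)
  expect_true("non-monotone time" %in% flagged$reason)
  expect_equal(unique(d$individual_id), "ok")
})

test_that("stage summaries compute the published statistic battery", {
  durs <- data.frame(individual_id = as.character(1:3), temperature_C = 20,
                     stage = "egg", duration_days = c(1, 2, 3),
                     completed = TRUE)
  row <- summarize_stage(durs, "egg", 20)
  expect_equal(row$mean_days, 2)
  expect_equal(row$sd_days, 1)
  expect_equal(row$median_days, 2)
  expect_equal(row$skewness, 0)
  expect_true(is.na(row$kurtosis))   # bias-adjusted form needs n >= 4
  expect_true(is.na(row$mode_days))  # all values unique
  durs2 <- durs
  durs2$duration_days <- c(2, 2, 4)
  expect_equal(summarize_stage(durs2, "egg", 20)$mode_days, 2)
})

test_that("relative survival reproduces the published worked example", {
  # 50 eggs entered at the coldest temperature, 13 completed
  durs <- data.frame(individual_id = as.character(1:50), temperature_C = 6,
                     stage = "egg", duration_days = 9,
                     completed = rep(c(TRUE, FALSE), c(13, 37)))
  row <- summarize_stage(durs, "egg", 6)
  expect_equal(round(row$relative_survival, 2), 0.26)
  expect_equal(relative_mortality(row), 0.74)
  expect_equal(relative_mortality(row) + row$relative_survival, 1)
})

test_that("relative mortality recomputes from the bundled study counts", {
  tab <- suzukii_stage_table()
  pick <- function(s, temp) tab[tab$stage == s & tab$temperature_C == temp, ]
  expect_equal(relative_mortality(pick("egg", 6)), 0.74)
  expect_equal(relative_mortality(pick("egg", 33)), 0.94)
  expect_equal(relative_mortality(pick("L3", 20)), 0)
  # survivor counts chain: entrants of each stage are the survivors of
  # the previous one, at every temperature
  stages <- c("egg", "L1", "L2", "L3", "pupa")
  for (temp in unique(tab$temperature_C)) {
    for (i in 1:4) {
      expect_equal(pick(stages[i + 1], temp)$n_entered,
                   pick(stages[i], temp)$n_survived)
    }
  }
})

test_that("duration-to-rate conversion is an exact reciprocal", {
  durs <- data.frame(individual_id = as.character(1:4), temperature_C = 26,
                     stage = "egg", duration_days = c(2, 0.8, 1.25, 3),
                     completed = c(TRUE, TRUE, TRUE, FALSE))
  r <- durations_to_rates(durs)
  expect_equal(nrow(r), 3)  # incomplete excluded
  expect_equal(r$rate_per_day[1:2], c(0.5, 1.25))
  expect_identical(1 / r$rate_per_day, durs$duration_days[durs$completed])
  durs$duration_days[1] <- 0
  expect_error(durations_to_rates(durs), "positive")
})

test_that("adult longevity is death minus emergence, split by sex", {
  rec <- rbind(
    simple_history(id = "m", times = c(0, 20, 42),
                   stages = c("pupa", "adult_male", "adult_male"),
                   alive = c(TRUE, TRUE, FALSE)),
    simple_history(id = "f", times = c(0, 18, 40),
                   stages = c("pupa", "adult_female", "adult_female"),
                   alive = c(TRUE, TRUE, FALSE)))
  lon <- adult_longevities(rec)
  expect_equal(lon$longevity_days[lon$sex == "male"], 22)
  expect_equal(lon$longevity_days[lon$sex == "female"], 22)
  tab <- adult_longevity_table(rec)
  expect_setequal(tab$sex, c("male", "female"))
  expect_false("relative_survival" %in% names(tab))
  # all-female input: male partition simply absent, no error
  tabf <- adult_longevity_table(rec[rec$individual_id == "f", ])
  expect_equal(tabf$sex, "female")
  # missing death observation excluded with a warning
  expect_warning(
    lon2 <- adult_longevities(
      simple_history(id = "g", times = c(0, 18, 30),
                     stages = c("pupa", "adult_female", "adult_female"),
                     alive = TRUE)),
    "no death")
  expect_equal(nrow(lon2), 0)
})

test_that("fecundity summary reads pre-oviposition and totals per female", {
  one <- data.frame(female_id = "f1", temperature_C = 24, day = 1:3,
                    eggs = c(0, 5, 3))
  s <- fecundity_summary(one)
  expect_equal(s$mean_preoviposition, 2)
  expect_equal(s$mean_total_eggs, 8)
  ten <- do.call(rbind, lapply(1:10, function(i)
    data.frame(female_id = paste0("f", i), temperature_C = 24, day = 1:3,
               eggs = c(0, 5, 3))))
  s10 <- fecundity_summary(ten)
  expect_equal(s10$n_females, 10)
  expect_equal(s10$se_total_eggs, 0)
  expect_equal(s10$se_preoviposition, 0)
  # a female that never laid: out of the pre-oviposition mean, a zero total
  with_barren <- rbind(one, data.frame(female_id = "f2", temperature_C = 24,
                                       day = 1:3, eggs = 0))
  expect_message(s2 <- fecundity_summary(with_barren), "no eggs")
  expect_equal(s2$mean_preoviposition, 2)
  expect_equal(s2$mean_total_eggs, 4)
})

test_that("the bundled egg-production table peaks at 24 C", {
  tab <- suzukii_fecundity_table()
  expect_equal(tab$temperature_C[which.max(tab$total_eggs_mean)], 24)
})

test_that("survivor counts never increase along the stage order", {
  g <- generate_cohort(generator_config(seed = 42), 25)
  lt <- stage_life_table(g$records)
  counts <- lt$n_entered[match(c("egg", "L1", "L2", "L3", "pupa"), lt$stage)]
  counts <- counts[!is.na(counts)]
  expect_true(all(diff(counts) <= 0))
  expect_true(all(lt$n_survived <= lt$n_entered))
})
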