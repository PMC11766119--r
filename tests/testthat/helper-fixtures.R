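# Shared fixtures built in code.

# A minimal inspection history: one individual observed daily.
simple_history <- function(id = "a", temp = 26,
                           times = c(0, 1, 2),
                           stages = c("egg", "L1", "L2"),
                           alive = TRUE) {
  data.frame(individual_id = id, temperature_C = temp, time_days = times,
             stage = stages, alive = alive)
}

# Degenerate generator tables: one temperature, every stage survived with
# probability 1 and a fixed (zero-variance) duration.
degenerate_stage_table <- function(temp = 13, means = c(3, 4, 5, 7, 13)) {
  data.frame(stage = c("egg", "L1", "L2", "L3", "pupa"),
             temperature_C = temp, mean_days = means, sd_days = 0,
             mode_days = NA, median_days = NA, kurtosis = NA, skewness = NA,
             n_entered = 50, n_survived = 50)
}

degenerate_adult_table <- function(temp = 13, mean_days = 20) {
  data.frame(sex = c("male", "female"), temperature_C = temp,
             mean_days = mean_days, sd_days = 0, mode_days = NA,
             median_days = NA, kurtosis = NA, skewness = NA)
}

degenerate_config <- function(temp = 13, seed = 1, cohort_size = 50, ...) {
  generator_config(temperatures = temp, cohort_size = cohort_size,
                   seed = seed,
                   stage_table = degenerate_stage_table(temp),
                   adult_table = degenerate_adult_table(temp),
                   ...)
}

# Random valid parameter sets per family, for property-style loops.
random_params <- function(key) {
  switch(key,
    logan = c(psi = runif(1, 0.01, 0.2), rho = runif(1, 0.05, 0.2),
              t_max = runif(1, 28, 38), delta_t = runif(1, 1, 8)),
    briere = c(a = 10^runif(1, -5, -3.5), m = runif(1, 1, 5),
               t_low = runif(1, 0, 10), t_max = runif(1, 28, 38)),
    lactin1 = c(a = runif(1, 0.05, 0.2), t_max = runif(1, 28, 40),
                delta_t = runif(1, 3, 12)),
    lactin2 = c(a = runif(1, 0.05, 0.2), t_max = runif(1, 28, 40),
                delta_t = runif(1, 3, 12), lam = runif(1, -0.5, 0.5)),
    kimlee = c(k = runif(1, 0.5, 1), rho_t = runif(1, 2, 10),
               t_opt_survival = runif(1, 15, 28)),
    fertility_gaussianlike = c(alpha = runif(1, 100, 5000),
                               gamma_ = runif(1, 1, 8),
                               lam = runif(1, 5, 20),
                               tau = runif(1, 18, 28),
                               delta = runif(1, 0, 10)),
    stop("no random generator for ", key))
}

# Dense-grid brute-force argmax: the independent oracle for the numeric
# optimum finder.
grid_argmax <- function(key, pars, interval = c(-5, 50), n = 10000) {
  fam <- rate_model(key)
  grid <- seq(interval[1], interval[2], length.out = n)
  grid[which.max(fam$fn(grid, pars))]
}

# Bathtub parameter set whose curve stays inside [0, 1] on 6-33 C.
bathtub_unit_params <- function() {
  c(am = 3.976e-6, bm = -2.798e-4, cm = 1.149e-2, dm = -0.2523, em = 2.107)
}

study_temperatures <- function() c(6, 9, 13, 18, 20, 24, 25, 26, 27, 28,
                                   29, 31, 32, 33)
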