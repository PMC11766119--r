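.PKG_VERSION <- function()
  as.character(utils::packageVersion("lifetherm"))

# Polynomial rolling hash of a deparsed object; enough to stamp outputs
# with the configuration that produced them.
.config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write / read a cohort or fecundity CSV
#'
#' Plain CSV in the long input schema, preceded by a `#` header comment
#' carrying the tool version, seed, and configuration hash so every
#' output records its provenance. Numeric columns are written with 17
#' significant digits, which round-trips doubles exactly.
#'
#' @param x Data frame of records.
#' @param path Output file path.
#' @param seed Seed recorded in the header.
#' @param config Object whose hash is recorded in the header.
#' @return `write_dataset_csv()` the path, invisibly;
#'   `read_dataset_csv()` the data frame.
#' @export
write_dataset_csv <- function(x, path, seed = NA, config = NULL) {
  header <- sprintf("# lifetherm %s seed=%s config=%s",
                    .PKG_VERSION(), seed,
                    if (is.null(config)) "none" else .config_hash(config))
  num <- vapply(x, is.numeric, logical(1)) & !vapply(x, is.integer, logical(1))
  x[num] <- lapply(x[num], function(col) sprintf("%.17g", col))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(x, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_dataset_csv
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#")
}

#' Validate an inspection-record table
#'
#' Schema and consistency checks on a long cohort table (or a CSV path):
#' required columns, the 7-value stage vocabulary, alive coded 0/1,
#' strictly increasing times per individual, legal stage order with no
#' skipped stage, no alive observation after death. Returns one
#' diagnostic row per violation; zero rows means the table is clean.
#'
#' @param x Data frame of records, or a path to a CSV readable by
#'   [read_dataset_csv()].
#' @return Data frame `individual_id`, `check`, `message`.
#' @export
validate_records <- function(x) {
  if (is.character(x)) x <- read_dataset_csv(x)
  need <- c("individual_id", "temperature_C", "time_days", "stage", "alive")
  miss <- setdiff(need, names(x))
  if (length(miss))
    return(data.frame(individual_id = NA_character_, check = "schema",
                      message = paste("missing columns:",
                                      paste(miss, collapse = ", "))))
  diags <- list()
  note <- function(id, check, msg)
    diags[[length(diags) + 1L]] <<- data.frame(individual_id = id,
                                               check = check, message = msg)
  bad_stage <- !x$stage %in% stage_levels()
  for (id in unique(x$individual_id[bad_stage]))
    note(id, "stage_vocabulary", "stage label outside the 7-value vocabulary")
  if (!all(x$alive %in% c(0, 1, TRUE, FALSE)))
    note(NA_character_, "alive_coding", "alive must be 0/1")
  vocab_ok <- !x$individual_id %in% unique(x$individual_id[bad_stage])
  for (sub in split(x[vocab_ok, , drop = FALSE],
                    x$individual_id[vocab_ok])) {
    id <- sub$individual_id[1]
    if (any(diff(sub$time_days) <= 0)) note(id, "time", "non-monotone time")
    r <- .stage_rank(sub$stage)
    if (any(diff(r) < 0)) note(id, "stage_order", "stage order regression")
    if (any(diff(r) > 1)) note(id, "stage_order", "skipped stage")
    dead <- which(!as.logical(sub$alive))
    if (length(dead) && any(as.logical(sub$alive)[seq_len(nrow(sub)) > min(dead)]))
      note(id, "status", "alive observation after death")
  }
  if (!length(diags))
    return(data.frame(individual_id = character(), check = character(),
                      message = character()))
  out <- do.call(rbind, diags)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' Simulate (optionally) -> validate -> life tables -> model fits ->
#' comparison, writing a reproducible report bundle: cohort and
#' fecundity CSVs, preimaginal and adult life-table CSVs, a fecundity
#' summary, per-fit parameter CSVs, a model-comparison CSV, and a run
#' log recording the seed, configuration hash and package version.
#' Identical inputs and seed regenerate the bundle bit-identically.
#'
#' @param out_dir Output directory (created if missing).
#' @param cfg A [generator_config()]; its seed drives both simulation
#'   and fitting.
#' @param records Optional pre-existing record data frame or CSV path;
#'   when supplied, simulation is skipped.
#' @param fecundity Optional fecundity data frame or CSV path.
#' @param stages Preimaginal stages to fit development models for.
#' @param dev_models Development families to fit (registry keys).
#' @param mort_models Mortality families to fit.
#' @param n_starts Multi-start budget per fit.
#' @return Invisibly, a list with the life tables, fit results,
#'   comparisons, and output paths.
#' @export
run_pipeline <- function(out_dir, cfg = generator_config(),
                         records = NULL, fecundity = NULL,
                         stages = c("egg", "L1", "L2", "L3", "pupa"),
                         dev_models = development_model_keys(),
                         mort_models = mortality_model_keys(),
                         n_starts = 64) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(label, expr) {
    tryCatch(expr, error = function(e)
      stop("[", label, "] ", conditionMessage(e), call. = FALSE))
  }
  if (is.null(records)) {
    sim <- step("simulate", generate_cohorts(cfg))
    records <- sim$records
    fec_ok <- cfg$fecundity_table$temperature_C[
      !is.na(cfg$fecundity_table$total_eggs_mean)]
    fecundity <- step("simulate", do.call(rbind, lapply(
      intersect(cfg$temperatures, fec_ok),
      function(temp) generate_fecundity(cfg, temp))))
  } else if (is.character(records)) {
    records <- step("read", read_dataset_csv(records))
    if (is.character(fecundity))
      fecundity <- step("read", read_dataset_csv(fecundity))
  }
  diags <- step("validate", validate_records(records))
  if (nrow(diags) > 0)
    warning(nrow(diags), " validation diagnostic(s); flagged individuals ",
            "are quarantined from the life tables")

  durations <- step("lifetable", extract_stage_durations(records))
  lt <- step("lifetable", stage_life_table(records, durations))
  adult_lt <- step("lifetable", adult_longevity_table(records))
  fec_sum <- if (!is.null(fecundity) && nrow(fecundity))
    step("lifetable", fecundity_summary(fecundity)) else NULL

  fits <- list(); comparisons <- list()
  for (s in intersect(stages, unique(durations$stage[durations$completed]))) {
    ds <- step("fit", build_development_dataset(durations, s))
    sf <- lapply(dev_models, function(k)
      step("fit", fit_model(ds, k, n_starts = n_starts, seed = cfg$seed)))
    names(sf) <- dev_models
    fits[[paste0("development_", s)]] <- sf
    if (length(sf) >= 2)
      comparisons[[paste0("development_", s)]] <- compare_models(sf)
    mds <- step("fit", build_mortality_dataset(lt, s))
    if (nrow(mds) > max(vapply(mort_models, function(k)
      length(rate_model(k)$par_names), numeric(1)))) {
      mf <- lapply(mort_models, function(k)
        step("fit", fit_model(mds, k, n_starts = n_starts, seed = cfg$seed)))
      names(mf) <- mort_models
      fits[[paste0("mortality_", s)]] <- mf
    }
  }
  lon <- step("fit", adult_longevities(records))
  for (sx in intersect(c("male", "female"), unique(lon$sex))) {
    lds <- step("fit", build_longevity_dataset(lon, sx))
    fits[[paste0("longevity_", sx)]] <-
      list(logan = step("fit", fit_model(lds, "logan", n_starts = n_starts,
                                         seed = cfg$seed)))
  }
  if (!is.null(fec_sum) && nrow(fec_sum) > 5) {
    fds <- build_fecundity_dataset(fec_sum)
    fits$fertility <- list(
      fertility_gaussianlike = step("fit", fit_model(
        fds, "fertility_gaussianlike", n_starts = n_starts,
        seed = cfg$seed)))
  }

  paths <- .write_bundle(out_dir, cfg, records, fecundity, lt, adult_lt,
                         fec_sum, fits, comparisons)
  invisible(list(life_table = lt, adult_table = adult_lt,
                 fecundity_summary = fec_sum, fits = fits,
                 comparisons = comparisons, diagnostics = diags,
                 paths = paths))
}

.write_bundle <- function(out_dir, cfg, records, fecundity, lt, adult_lt,
                          fec_sum, fits, comparisons) {
  p <- function(...) file.path(out_dir, ...)
  paths <- c(records = p("records.csv"), life_table = p("life_table.csv"),
             adult_table = p("adult_longevity.csv"),
             comparison = p("model_comparison.csv"),
             fit_parameters = p("fit_parameters.csv"), log = p("run_log.txt"))
  write_dataset_csv(records, paths[["records"]], cfg$seed, cfg)
  write_dataset_csv(.round_display(lt), paths[["life_table"]], cfg$seed, cfg)
  write_dataset_csv(.round_display(adult_lt), paths[["adult_table"]],
                    cfg$seed, cfg)
  if (!is.null(fecundity) && nrow(fecundity)) {
    paths <- c(paths, fecundity = p("fecundity.csv"),
               fecundity_summary = p("fecundity_summary.csv"))
    write_dataset_csv(fecundity, paths[["fecundity"]], cfg$seed, cfg)
    write_dataset_csv(.round_display(fec_sum), paths[["fecundity_summary"]],
                      cfg$seed, cfg)
  }
  par_rows <- list()
  for (group in names(fits)) for (key in names(fits[[group]])) {
    f <- fits[[group]][[key]]
    if (!f$converged) next
    par_rows[[paste(group, key)]] <- data.frame(
      dataset = group, model = key, parameter = names(f$estimates),
      estimate = unname(f$estimates), std_error = unname(f$std_errors),
      r_squared = f$r_squared, rmse = f$rmse, chi_squared = f$chi_squared,
      ndf = f$ndf)
  }
  if (length(par_rows))
    write_dataset_csv(do.call(rbind, par_rows), paths[["fit_parameters"]],
                      cfg$seed, cfg)
  if (length(comparisons)) {
    cmp <- do.call(rbind, Map(function(nm, tab)
      cbind(dataset = nm, as.data.frame(tab)), names(comparisons),
      comparisons))
    write_dataset_csv(cmp, paths[["comparison"]], cfg$seed, cfg)
  }
  writeLines(c(sprintf("lifetherm %s", .PKG_VERSION()),
               sprintf("seed: %s", cfg$seed),
               sprintf("config: %s", .config_hash(cfg)),
               sprintf("records: %d rows, %d individuals", nrow(records),
                       length(unique(records$individual_id))),
               sprintf("fits: %s", paste(names(fits), collapse = ", "))),
             paths[["log"]])
  paths
}

# Display rounding mirrors the published tables (survival to 2 decimals,
# times to 2); full precision stays in the in-memory objects.
.round_display <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = 2)
  df
}
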