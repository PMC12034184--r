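# Fixed CSV dialect throughout: comma-separated, UTF-8, '.' decimal,
# ISO 8601 dates, mandatory header row. No sniffing.

.sex_levels <- c("male", "female", "all")
.age_levels <- c("25-64", "65-84", "85+", "all")

#' Read a daily mortality-temperature series
#'
#' Schema: `date` (ISO 8601), `deaths` (non-negative integer, empty for
#' missing), `tmean` (degrees C), optional `sex` and `age_group` stratum
#' labels. Malformed rows are reported with their line numbers; duplicate
#' (date, stratum) combinations and unknown stratum labels are errors.
#'
#' @param path CSV file path.
#' @return data.frame with typed columns.
#' @export
read_daily_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", fileEncoding = "UTF-8")
  need <- c("date", "deaths", "tmean")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("read_daily_series: missing columns: ",
         paste(missing_cols, collapse = ", "))
  line <- seq_len(nrow(df)) + 1L  # header is line 1
  date <- as.Date(df$date, format = "%Y-%m-%d")
  if (anyNA(date))
    stop("read_daily_series: unparseable date at line ",
         paste(utils::head(line[is.na(date)], 5L), collapse = ", "))
  deaths <- suppressWarnings(as.numeric(df$deaths))
  bad <- !is.na(deaths) & (deaths < 0 | deaths != round(deaths))
  bad[df$deaths != "" & is.na(deaths)] <- TRUE
  if (any(bad))
    stop("read_daily_series: deaths must be a non-negative integer or ",
         "empty; offending line ",
         paste(utils::head(line[bad], 5L), collapse = ", "))
  tmean <- suppressWarnings(as.numeric(df$tmean))
  if (any(df$tmean != "" & is.na(tmean)))
    stop("read_daily_series: unparseable tmean at line ",
         paste(utils::head(line[df$tmean != "" & is.na(tmean)], 5L),
               collapse = ", "))
  out <- data.frame(date = date, deaths = as.integer(deaths), tmean = tmean)
  for (col in c("sex", "age_group")) {
    if (col %in% names(df)) {
      valid <- if (col == "sex") .sex_levels else .age_levels
      bad_lab <- setdiff(unique(df[[col]]), valid)
      if (length(bad_lab))
        stop("read_daily_series: unknown ", col, " label ",
             paste(sQuote(bad_lab), collapse = ", "),
             "; valid labels: ", paste(valid, collapse = ", "))
      out[[col]] <- df[[col]]
    }
  }
  key <- do.call(paste, c(out[intersect(c("date", "sex", "age_group"),
                                        names(out))], sep = "|"))
  if (anyDuplicated(key))
    stop("read_daily_series: duplicate (date, stratum) at line ",
         paste(utils::head(line[duplicated(key)], 5L), collapse = ", "))
  out
}

#' Write a daily series CSV
#' @param series data.frame as returned by [read_daily_series()] or the
#'   generators.
#' @param path output path.
#' @export
write_daily_series <- function(series, path) {
  out <- series
  out$date <- format(out$date, "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Read survey microdata CSV
#' @param path CSV path with the [simulate_survey()] schema.
#' @return data.frame.
#' @export
read_survey_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' Write survey microdata CSV
#' @param records survey data.frame.
#' @param path output path.
#' @export
write_survey_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write the epi pipeline's result files
#'
#' `rr_table.csv` (stratum, percentile, temp, rr, ci_low, ci_high),
#' `curves.csv` (stratum, temp, log_rr, se), `mmt.csv` (stratum, mmt_temp,
#' mmt_percentile) and `fit_diagnostics.csv` (stratum, dispersion, n_obs,
#' n_params, converged, n_iter).
#'
#' @param results a [run_city()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_city_results <- function(results, dir) {
  stopifnot(inherits(results, "city_results"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(rr_table(results), file.path(dir, "rr_table.csv"),
                   row.names = FALSE, quote = FALSE)
  all_strata <- c(list(results$overall), Filter(function(s)
    inherits(s, "stratum_result"), results$strata))
  curves <- do.call(rbind, lapply(all_strata, function(s)
    data.frame(stratum = s$label, temp = s$curve$temp_grid,
               log_rr = s$curve$log_rr, se = s$curve$se)))
  utils::write.csv(curves, file.path(dir, "curves.csv"), row.names = FALSE,
                   quote = FALSE)
  mmts <- do.call(rbind, lapply(all_strata, function(s)
    data.frame(stratum = s$label, mmt_temp = s$mmt$mmt_temp,
               mmt_percentile = s$mmt$mmt_percentile)))
  utils::write.csv(mmts, file.path(dir, "mmt.csv"), row.names = FALSE,
                   quote = FALSE)
  diags <- do.call(rbind, lapply(all_strata, function(s)
    data.frame(stratum = s$label, dispersion = s$fit$dispersion,
               n_obs = s$fit$n_obs, n_params = s$fit$n_params,
               converged = s$fit$converged, n_iter = s$fit$n_iter)))
  utils::write.csv(diags, file.path(dir, "fit_diagnostics.csv"),
                   row.names = FALSE, quote = FALSE)
  failed <- names(results$strata)[!vapply(results$strata, inherits,
                                          logical(1), "stratum_result")]
  if (length(failed))
    writeLines(paste(failed, unlist(results$strata[failed]), sep = ": "),
               file.path(dir, "failed_strata.txt"))
  invisible(dir)
}

#' Write the survey fit's result files
#'
#' `survey_fit.csv` (term, estimate, robust_se, t, p, stars), `vif.csv`,
#' `drops.csv`.
#' @param sf a [run_survey_model()] result.
#' @param dir output directory.
#' @return invisibly, the directory.
#' @export
write_survey_results <- function(sf, dir) {
  stopifnot(inherits(sf, "survey_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sf$tidy, file.path(dir, "survey_fit.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(term = names(sf$vif), vif = unname(sf$vif)),
                   file.path(dir, "vif.csv"), row.names = FALSE, quote = FALSE)
  utils::write.csv(sf$drops, file.path(dir, "drops.csv"), row.names = FALSE)
  invisible(dir)
}

# effective-config echo: every run directory gets the merged config so the
# run can be reproduced bit-identically
.echo_config <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(dir, "effective_config.yaml"))
}

#' Read a structured run configuration
#'
#' YAML with top-level keys `mode` (simulate-epi, fit-epi, simulate-survey,
#' fit-survey, paradox), `seed`, `input`/`output` paths, and mode-specific
#' blocks (`epi_sim`, `analysis`, `survey_sim`, `paradox`). Unknown
#' top-level keys are rejected.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- yaml::read_yaml(path)
  known <- c("mode", "seed", "input", "survey_input", "mapping", "output",
             "epi_sim", "analysis", "survey_sim", "weighted", "city")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("read_run_config: unknown keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$mode)) stop("read_run_config: 'mode' is required")
  cfg
}

.build_epi_sim_config <- function(cfg, seed) {
  es <- cfg$epi_sim
  if (!is.null(es$city)) {
    base <- switch(es$city, warsaw = warsaw_epi_config(seed),
                   madrid = madrid_epi_config(seed),
                   stop("unknown city profile: ", es$city))
  } else stop("epi_sim block must name a 'city' profile (warsaw or madrid)")
  for (f in c("rr90", "rr99", "cold_rr", "mmt_temp", "baseline_daily_deaths",
              "seasonal_baseline_amplitude", "overdispersion"))
    if (!is.null(es[[f]])) base[[f]] <- es[[f]]
  base
}

.build_analysis_config <- function(cfg) {
  a <- cfg$analysis
  if (is.null(a)) return(analysis_config())
  do.call(analysis_config, a)
}

#' Execute one configured pipeline stage
#'
#' Dispatches on `cfg$mode`; all randomness flows from the single `seed`
#' (the `--seed` flag overrides the config's). Every output directory gets
#' an `effective_config.yaml` echo sufficient to reproduce the run.
#'
#' @param cfg list from [read_run_config()].
#' @param seed optional integer overriding `cfg$seed`.
#' @return invisibly, the primary result object.
#' @export
run_config <- function(cfg, seed = NULL) {
  seed <- as.integer(if (!is.null(seed)) seed else
    if (!is.null(cfg$seed)) cfg$seed else 1L)
  out_dir <- if (!is.null(cfg$output)) cfg$output else "."
  cfg$seed <- seed
  res <- switch(cfg$mode,
    "simulate-epi" = {
      sim <- simulate_city(.build_epi_sim_config(cfg, seed), seed = seed)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_daily_series(sim$series, file.path(out_dir, "daily_series.csv"))
      sim
    },
    "fit-epi" = {
      series <- read_daily_series(cfg$input)
      results <- run_city(series, .build_analysis_config(cfg))
      write_city_results(results, out_dir)
      results
    },
    "simulate-survey" = {
      sc <- survey_sim_config(seed = seed)
      if (!is.null(cfg$survey_sim$n)) sc$n <- as.integer(cfg$survey_sim$n)
      if (!is.null(cfg$survey_sim$intercept))
        sc$intercept <- cfg$survey_sim$intercept
      if (!is.null(cfg$survey_sim$residual_sd))
        sc$residual_sd <- cfg$survey_sim$residual_sd
      tab <- simulate_survey(sc, seed = seed)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      write_survey_csv(tab, file.path(out_dir, "survey.csv"))
      tab
    },
    "fit-survey" = {
      records <- read_survey_csv(cfg$input)
      weighted <- if (is.null(cfg$weighted)) TRUE else isTRUE(cfg$weighted)
      sf <- run_survey_model(records, weighted = weighted)
      write_survey_results(sf, out_dir)
      sf
    },
    "paradox" = {
      rr <- utils::read.csv(cfg$input, stringsAsFactors = FALSE)
      survey <- utils::read.csv(cfg$survey_input, stringsAsFactors = FALSE)
      mapping <- utils::read.csv(cfg$mapping, stringsAsFactors = FALSE)
      rep_ <- paradox_report(rr, survey, mapping)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.csv(rep_, file.path(out_dir, "paradox_report.csv"),
                       row.names = FALSE, quote = FALSE)
      rep_
    },
    stop("unknown mode: ", cfg$mode)
  )
  .echo_config(cfg, out_dir)
  invisible(res)
}

#' Command-line entry point
#'
#' `heatparadox-cli.R <mode> --config <file> [--seed <int>] [--out <dir>]`.
#' Returns exit status 0 on success; any error is reported as a one-line
#' diagnostic on stderr with a non-zero status.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status (invisibly).
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: <simulate-epi|fit-epi|simulate-survey|fit-survey|paradox>",
                 "--config <file> [--seed <int>] [--out <dir>]")
  status <- tryCatch({
    if (length(argv) < 1L) stop(usage)
    mode <- argv[1]
    get_opt <- function(flag) {
      i <- which(argv == flag)
      if (length(i) == 1L && i < length(argv)) argv[i + 1L] else NULL
    }
    config_path <- get_opt("--config")
    if (is.null(config_path)) stop(usage)
    cfg <- read_run_config(config_path)
    cfg$mode <- mode
    out <- get_opt("--out")
    if (!is.null(out)) cfg$output <- out
    seed <- get_opt("--seed")
    run_config(cfg, seed = if (!is.null(seed)) as.integer(seed) else NULL)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
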