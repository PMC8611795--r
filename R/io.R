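# provenance comment lines written at the top of every CSV artifact
.provenance_header <- function(seed = NULL, config_hash = NULL) {
  ver <- as.character(utils::packageVersion("pelletpulse"))
  parts <- c(sprintf("pelletpulse %s", ver),
             if (!is.null(seed)) sprintf("seed=%s", seed),
             if (!is.null(config_hash)) sprintf("config_hash=%s", config_hash))
  paste("#", paste(parts, collapse = "; "))
}

.write_csv_with_header <- function(df, path, seed = NULL, config_hash = NULL) {
  writeLines(.provenance_header(seed, config_hash), path)
  readr::write_csv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write a probe dataset (or replicate readings) to CSV
#'
#' Two layouts are supported, mirroring how probe data circulate: the
#' aggregated mean/SD layout (`probe_id`, `depth_mm`, `window_start_h`,
#' `window_end_h`, `mean_ug_ml`, `sd_ug_ml`, `n`) and the replicate-level
#' readings layout (`probe_id`, `depth_mm`, `window_start_h`,
#' `window_end_h`, `volume_ml`, `concentration_ug_ml`, `censored`,
#' `replicate`). The layout is inferred from the columns present.
#'
#' @param dataset A tibble in either layout.
#' @param path Output CSV path.
#' @param seed,config_hash Optional provenance stamped in a comment line.
#' @return `path`, invisibly.
#' @export
write_probe_dataset <- function(dataset, path, seed = attr(dataset, "seed"),
                                config_hash = NULL) {
  .write_csv_with_header(dataset, path, seed, config_hash)
}

#' Read a probe dataset from CSV
#'
#' Accepts both layouts written by [write_probe_dataset()]; replicate-level
#' files are aggregated to the mean/SD layout (the replicate table is kept
#' in `attr(, "replicates")`). Column units are part of the header names
#' (`_mm`, `_h`, `_ug_ml`) and are validated; malformed or negative
#' concentrations are rejected with their line numbers.
#'
#' @param path CSV path (UTF-8, dot decimal, `#` comment lines ignored).
#' @return A probe dataset tibble.
#' @export
read_probe_dataset <- function(path) {
  if (!file.exists(path))
    abort(sprintf("File not found: %s", path), class = "pelletpulse_io_error")
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  base_cols <- c("depth_mm", "window_start_h", "window_end_h")
  if (!all(base_cols %in% names(df)))
    abort(sprintf(
      "Missing required columns (units are encoded in the names): %s.",
      paste(setdiff(base_cols, names(df)), collapse = ", ")),
      class = "pelletpulse_io_error")
  replicate_layout <- "concentration_ug_ml" %in% names(df)
  mean_layout <- all(c("mean_ug_ml", "sd_ug_ml") %in% names(df))
  if (!replicate_layout && !mean_layout)
    abort("Need either `concentration_ug_ml` (replicate layout) or `mean_ug_ml` + `sd_ug_ml` (aggregated layout).",
          class = "pelletpulse_io_error")
  conc_col <- if (replicate_layout) "concentration_ug_ml" else "mean_ug_ml"
  bad <- which(!is.finite(df[[conc_col]]) | df[[conc_col]] < 0)
  if (length(bad) > 0)
    abort(sprintf(
      "Negative or non-numeric concentrations at data line(s): %s.",
      paste(head(bad, 10), collapse = ", ")),
      class = "pelletpulse_io_error")
  if (mean_layout && any(df$sd_ug_ml < 0, na.rm = TRUE))
    abort("Negative standard deviations are not allowed.",
          class = "pelletpulse_io_error")
  if (!replicate_layout) {
    if (!"probe_id" %in% names(df))
      df$probe_id <- paste0("P", match(df$depth_mm, sort(unique(df$depth_mm))))
    if (!"n" %in% names(df)) df$n <- NA_integer_
    return(df %>% arrange(.data$depth_mm, .data$window_start_h))
  }
  if (!"probe_id" %in% names(df))
    df$probe_id <- paste0("P", match(df$depth_mm, sort(unique(df$depth_mm))))
  out <- df %>%
    group_by(.data$probe_id, .data$depth_mm, .data$window_start_h,
             .data$window_end_h) %>%
    summarise(mean_ug_ml = mean(.data$concentration_ug_ml),
              sd_ug_ml = if (n() > 1) sd(.data$concentration_ug_ml) else 0,
              n = n(),
              frac_censored = if ("censored" %in% names(df))
                mean(.data$censored) else 0,
              .groups = "drop") %>%
    arrange(.data$depth_mm, .data$window_start_h)
  attr(out, "replicates") <- df
  out
}

#' Export a column solution as tidy CSV
#'
#' @param solution A `column_solution`.
#' @param path Output CSV path.
#' @param seed,config_hash Optional provenance.
#' @return `path`, invisibly.
#' @export
write_solution_csv <- function(solution, path, seed = NULL,
                               config_hash = NULL) {
  .write_csv_with_header(tidy(solution), path, seed, config_hash)
}

#' Export a total-P profile as CSV
#'
#' @param profile Profile tibble from [predict_total_p_profile()] or
#'   [generate_total_p_profile()].
#' @param path Output CSV path.
#' @param seed,config_hash Optional provenance.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path, seed = NULL, config_hash = NULL) {
  .write_csv_with_header(profile, path, seed, config_hash)
}

#' Write a fit result as JSON
#'
#' Parameters are reported in their working units (SI rates and diffusivity,
#' mm geometry, ug P ml^-1 concentrations) together with the objective,
#' percent fit error, convergence diagnostics and provenance.
#'
#' @param fit A `pellet_fit`.
#' @param path Output JSON path.
#' @param seed,config_hash Optional provenance.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, seed = NULL, config_hash = NULL) {
  stopifnot(inherits(fit, "pellet_fit"))
  est <- setNames(as.list(fit$par_table$estimate), fit$par_table$term)
  payload <- list(
    parameters = est,
    units = list(diffusivity = "m2 s-1", adsorption_rate = "s-1",
                 desorption_rate = "s-1", peak = "ug P ml-1",
                 spread_above = "mm", spread_below = "mm"),
    objective = fit$objective,
    fit_error_percent = fit$fit_error_percent,
    n_obs = fit$n_obs,
    converged = fit$converged,
    n_function_evals = fit$n_function_evals,
    at_bound = as.list(setNames(fit$par_table$at_bound, fit$par_table$term)),
    provenance = list(package = "pelletpulse",
                      version = as.character(utils::packageVersion("pelletpulse")),
                      seed = seed, config_hash = config_hash)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full synthetic-experiment pipeline
#'
#' Executes simulate, generate, fit and report end-to-end from a single
#' configuration: forward-solves the generating truth, synthesizes the
#' replicate probe dataset and end-of-run total-P profile, fits the model to
#' the synthetic data and assembles the fit report. With `out_dir` set, all
#' artifacts are written (solution, readings, dataset, profile, fit JSON,
#' report CSVs and summary), each stamped with the configuration hash and
#' seed. Reruns with the same configuration and seed are identical.
#'
#' @param config A `run_config` from [load_config()], or a path to one.
#' @param out_dir Optional output directory (created if missing).
#' @param seed Seed overriding `config$seed`.
#' @param refine_method Passed to [fit_parameters()].
#' @return A list with `solution`, `dataset`, `replicates`, `profile`,
#'   `fit`, `report` and `provenance`.
#' @export
run_pipeline <- function(config = load_config(list()), out_dir = NULL,
                         seed = NULL, refine_method = "lsoda") {
  if (is.character(config)) config <- load_config(config)
  if (!inherits(config, "run_config")) config <- load_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  hash <- rlang::hash(unclass(config))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "pelletpulse_pipeline_error", parent = e)
    })
  }
  ob <- stage("configure", config_objects(config))
  sol <- stage("simulate", solve_transport(
    ob$params, ob$pulse, ob$grid,
    output_times_h = schedule_output_times(ob$schedule), method = "modal"))
  gen <- stage("generate", generate_dataset(
    ob$params, ob$pulse, ob$probes, ob$schedule, ob$calib, ob$noise,
    grid = ob$grid))
  profile <- stage("generate", generate_total_p_profile(
    ob$params, ob$pulse, ob$soil,
    noise = ob$noise, grid = ob$grid,
    end_time_h = max(ob$schedule$window_end_h)))
  fit <- stage("fit", fit_parameters(gen$dataset, ob$fit_config, ob$grid,
                                     refine_method = refine_method))
  report <- stage("report", fit_report(fit))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    save_config(config, p("config.yaml"))
    write_solution_csv(sol, p("solution.csv"), config$seed, hash)
    write_probe_dataset(gen$replicates, p("readings.csv"), config$seed, hash)
    write_probe_dataset(gen$dataset, p("dataset.csv"), config$seed, hash)
    write_profile_csv(profile, p("profile.csv"), config$seed, hash)
    write_fit_json(fit, p("fit.json"), config$seed, hash)
    .write_csv_with_header(report$curves, p("report_curves.csv"),
                           config$seed, hash)
    .write_csv_with_header(report$observations, p("report_observations.csv"),
                           config$seed, hash)
    writeLines(c(.provenance_header(config$seed, hash), report$summary),
               p("summary.txt"))
  }
  list(solution = sol, dataset = gen$dataset, replicates = gen$replicates,
       profile = profile, fit = fit, report = report,
       provenance = list(seed = config$seed, config_hash = hash,
                         version = as.character(utils::packageVersion("pelletpulse"))))
}
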