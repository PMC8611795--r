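.default_config <- function() {
  list(
    column = list(length_mm = 70, n_nodes = 401, pellet_depth_mm = 15,
                  break_depth_mm = 27.5),
    soil = list(bulk_density = 1.02, particle_density = 2.65,
                background_total_p = 597),
    transport = list(D_m2_s = 1.6e-11, beta1_s = 2.7e-6, beta2_s = 5.2e-9),
    pulse = list(c_pulse = 900, a_mm = 3, b_mm = 12, adsorbed_background = 0),
    probes = list(device = "microdialysis", depths_mm = NULL,
                  flow_rate_ul_min = NULL),
    schedule = list(total_duration_h = 336, high_res_window_h = 12,
                    high_res_step_h = 2, daily_perfusion_h = 12),
    calibration = list(gain = NULL, recovery_exponent = NULL,
                       detection_limit = 0.01),
    noise = list(probe_bias_cv = 0.06, measurement_cv = 0.02,
                 n_replicates = 3, distribution = "lognormal"),
    fit = list(fit_start_time_h = 8, sigma_floor = 0.05, multistart = 5,
               mode = "window_average",
               D_init = 1.9e-11, beta1_init = 3.1e-6, beta2_init = 3.6e-9,
               c_pulse_init = 850, a_init = 3, b_init = 12),
    seed = 1,
    output_dir = NULL
  )
}

# merge user values into defaults, rejecting unknown keys by name
.merge_config <- function(defaults, user, path = character()) {
  for (key in names(user)) {
    full <- paste(c(path, key), collapse = "$")
    if (!key %in% names(defaults))
      abort(sprintf("Unknown configuration key: `%s`.", full),
            class = "pelletpulse_config_error")
    if (is.list(defaults[[key]]) && !is.null(user[[key]])) {
      if (!is.list(user[[key]]))
        abort(sprintf("Configuration section `%s` must be a mapping.", full),
              class = "pelletpulse_config_error")
      defaults[[key]] <- .merge_config(defaults[[key]], user[[key]],
                                       c(path, key))
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration driving all pipeline stages (sections
#' `column`, `soil`, `transport`, `pulse`, `probes`, `schedule`,
#' `calibration`, `noise`, `fit`, plus `seed` and `output_dir`). Missing
#' values take the package defaults (the reference coarse-soil experiment);
#' unknown keys are rejected by name; all section invariants are checked by
#' constructing the typed objects.
#'
#' @param path Path to a YAML file, or a list of the same structure.
#' @return A validated configuration list of class `run_config`.
#' @seealso [config_objects()] to materialize the typed model objects,
#'   [save_config()] for the round trip.
#' @export
load_config <- function(path) {
  user <- if (is.list(path)) path else {
    if (!file.exists(path))
      abort(sprintf("Configuration file not found: %s", path),
            class = "pelletpulse_config_error")
    yaml::read_yaml(path)
  }
  cfg <- .merge_config(.default_config(), user)
  class(cfg) <- "run_config"
  config_objects(cfg) # side effect: validates every section invariant
  cfg
}

#' Save a run configuration to YAML
#'
#' @param config A `run_config` (or compatible list).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Materialize typed model objects from a configuration
#'
#' @param config A `run_config` from [load_config()].
#' @return A list with elements `grid`, `soil`, `params`, `pulse`, `probes`,
#'   `schedule`, `calib`, `noise`, `fit_config` and `seed`.
#' @export
config_objects <- function(config) {
  cc <- config$column
  grid <- column_grid(cc$length_mm, cc$n_nodes)
  soil <- soil_spec(config$soil$bulk_density, config$soil$particle_density,
                    config$soil$background_total_p)
  params <- transport_params(config$transport$D_m2_s,
                             config$transport$beta1_s,
                             config$transport$beta2_s)
  pulse <- initial_pulse(peak = config$pulse$c_pulse,
                         spread_above = config$pulse$a_mm,
                         spread_below = config$pulse$b_mm,
                         pellet_depth = cc$pellet_depth_mm,
                         break_depth = cc$break_depth_mm,
                         adsorbed_background = config$pulse$adsorbed_background)
  if (pulse$break_depth >= grid$length_mm)
    abort("`break_depth_mm` must lie inside the column.",
          class = "pelletpulse_config_error")
  pr <- config$probes
  probes <- probe_set(pellet_depth_mm = cc$pellet_depth_mm,
                      device = pr$device,
                      depth_mm = if (is.null(pr$depths_mm)) NULL else
                        as.numeric(pr$depths_mm),
                      flow_rate_ul_min = pr$flow_rate_ul_min)
  if (any(probes$depth_mm >= grid$length_mm))
    abort("Probe depths must lie inside the column.",
          class = "pelletpulse_config_error")
  sc <- config$schedule
  schedule <- build_schedule(sc$total_duration_h, sc$high_res_window_h,
                             sc$high_res_step_h, sc$daily_perfusion_h,
                             flow_rate_ul_min = probes$flow_rate_ul_min[1])
  cal <- config$calibration
  calib <- calibration_model(device = pr$device, gain = cal$gain,
                             recovery_exponent = cal$recovery_exponent,
                             detection_limit = cal$detection_limit)
  nz <- config$noise
  noise <- noise_model(nz$probe_bias_cv, nz$measurement_cv, nz$n_replicates,
                       seed = config$seed, distribution = nz$distribution)
  ft <- config$fit
  fitc <- fit_config(
    params_init = transport_params(ft$D_init, ft$beta1_init, ft$beta2_init),
    pulse_init = initial_pulse(peak = ft$c_pulse_init,
                               spread_above = ft$a_init,
                               spread_below = ft$b_init,
                               pellet_depth = cc$pellet_depth_mm,
                               break_depth = cc$break_depth_mm,
                               adsorbed_background = config$pulse$adsorbed_background),
    fit_start_time_h = ft$fit_start_time_h, sigma_floor = ft$sigma_floor,
    mode = ft$mode, multistart = ft$multistart, seed = config$seed)
  list(grid = grid, soil = soil, params = params, pulse = pulse,
       probes = probes, schedule = schedule, calib = calib, noise = noise,
       fit_config = fitc, seed = config$seed)
}
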