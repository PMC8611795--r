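#' Probe set for a column experiment
#'
#' Builds the tibble of sampling probes. The default layout is the
#' three-probe coarse-soil arrangement: one probe 5 mm above the pellet and
#' two probes 15 mm and 30 mm below it, microdialysis probes perfused at
#' 3.3 ul min^-1 (suction cups operate at 33 ul min^-1).
#'
#' @param pellet_depth_mm Pellet depth used to place the default probes, mm.
#' @param device `"microdialysis"` or `"suction_cup"`.
#' @param probe_id,depth_mm,flow_rate_ul_min Optional explicit probe
#'   definitions (equal-length vectors) overriding the default layout.
#' @return A tibble with columns `probe_id`, `depth_mm`, `device`,
#'   `flow_rate_ul_min`.
#' @examples
#' probe_set()
#' @export
probe_set <- function(pellet_depth_mm = 15,
                      device = c("microdialysis", "suction_cup"),
                      probe_id = NULL, depth_mm = NULL,
                      flow_rate_ul_min = NULL) {
  device <- match.arg(device)
  if (is.null(flow_rate_ul_min))
    flow_rate_ul_min <- if (device == "microdialysis") 3.3 else 33
  if (is.null(depth_mm)) {
    depth_mm <- pellet_depth_mm + c(-5, 15, 30)
    if (is.null(probe_id)) probe_id <- c("P1", "P2", "P3")
  }
  if (is.null(probe_id)) probe_id <- paste0("P", seq_along(depth_mm))
  if (length(probe_id) != length(depth_mm))
    abort("`probe_id` and `depth_mm` must have the same length.")
  if (any(depth_mm <= 0))
    abort("Probe depths must be positive (below the soil surface).")
  tibble(probe_id = as.character(probe_id), depth_mm = as.numeric(depth_mm),
         device = device,
         flow_rate_ul_min = rep_len(as.numeric(flow_rate_ul_min),
                                    length(depth_mm)))
}

#' Build the probe sampling schedule
#'
#' High-resolution sampling first (consecutive short perfusions), then one
#' long perfusion per day for the remainder of the experiment. The defaults
#' reproduce the two-week coarse-soil protocol: six 2-h samples in the first
#' 12 h, then a 12-h perfusion ending at each subsequent day boundary
#' (first daily window 36-48 h), 19 windows in all over 336 h. Sample volume
#' is `flow_rate x duration`.
#'
#' @param total_duration_h Experiment duration, hours (default 336 = 2 wk).
#' @param high_res_window_h Length of the initial high-resolution phase, h.
#' @param high_res_step_h Perfusion length within the high-resolution phase, h.
#' @param daily_perfusion_h Perfusion length of the daily samples, h.
#' @param flow_rate_ul_min Perfusion flow rate, ul min^-1.
#' @return A tibble with columns `window_start_h`, `window_end_h`,
#'   `volume_ml`.
#' @examples
#' build_schedule() # 6 x 2 h then 13 daily 12 h windows
#' @export
build_schedule <- function(total_duration_h = 336, high_res_window_h = 12,
                           high_res_step_h = 2, daily_perfusion_h = 12,
                           flow_rate_ul_min = 3.3) {
  stopifnot(total_duration_h > 0, high_res_window_h >= 0,
            high_res_step_h > 0, daily_perfusion_h > 0, daily_perfusion_h <= 24,
            flow_rate_ul_min > 0)
  n_high <- high_res_window_h / high_res_step_h
  if (abs(n_high - round(n_high)) > 1e-9)
    abort(sprintf(
      "`high_res_step_h` (%g) must divide `high_res_window_h` (%g).",
      high_res_step_h, high_res_window_h), class = "pelletpulse_config_error")
  n_high <- round(n_high)
  starts <- (seq_len(n_high) - 1) * high_res_step_h
  ends <- starts + high_res_step_h
  day_ends <- seq(48, total_duration_h, by = 24)
  day_ends <- day_ends[day_ends >= high_res_window_h + daily_perfusion_h]
  starts <- c(starts, day_ends - daily_perfusion_h)
  ends <- c(ends, day_ends)
  tibble(window_start_h = starts, window_end_h = ends,
         volume_ml = flow_rate_ul_min * (ends - starts) * 60 / 1000)
}

# output times at which a solution must be stored so that every window can be
# averaged accurately; Simpson nodes per window plus t = 0.
schedule_output_times <- function(schedule, points_per_window = 9) {
  pts <- unlist(purrr::map2(schedule$window_start_h, schedule$window_end_h,
                            ~seq(.x, .y, length.out = points_per_window)))
  sort(unique(c(0, pts)))
}
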