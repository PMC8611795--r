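# dissolved concentration at arbitrary depths/times: exact via the modal
# evaluator when available, else bilinear interpolation of the stored fields.
.eval_dissolved <- function(solution, depths_mm, times_h) {
  grid <- solution$grid
  if (any(depths_mm < 0 | depths_mm > grid$length_mm))
    abort("Probe depth outside the column.")
  tr <- range(solution$times_h)
  if (any(times_h < tr[1] - 1e-9 | times_h > tr[2] + 1e-9))
    abort(sprintf("Requested times outside the simulated range %g-%g h.",
                  tr[1], tr[2]), class = "pelletpulse_sampling_error")
  if (!is.null(solution$evaluator))
    return(solution$evaluator(depths_mm, times_h))
  # depth interpolation (linear between nodes), then time interpolation
  nd <- length(depths_mm); nt <- length(solution$times_h)
  at_depth <- matrix(0, nd, nt)
  for (j in seq_len(nt))
    at_depth[, j] <- approx(grid$z_mm, solution$dissolved[, j],
                            xout = depths_mm, rule = 2)$y
  out <- matrix(0, nd, length(times_h))
  for (i in seq_len(nd))
    out[i, ] <- approx(solution$times_h, at_depth[i, ],
                       xout = times_h, rule = 2)$y
  out
}

#' Virtual probe readings from a column solution
#'
#' Reads the dissolved-phosphorus field the way the samplers would: the
#' probes are passive observers (no phosphorus is removed from the column).
#' `window_average` integrates the concentration at the probe depth over the
#' perfusion window (composite Simpson quadrature) and divides by its length,
#' emulating a sample that accumulates over the whole perfusion;
#' `midpoint` reads the instantaneous concentration at the window centre.
#'
#' @param solution A `column_solution`.
#' @param probes A probe tibble from [probe_set()].
#' @param schedule A schedule tibble from [build_schedule()].
#' @param mode `"window_average"` (default) or `"midpoint"`.
#' @param n_quad Number of Simpson subintervals per window (even).
#' @return A tibble with columns `probe_id`, `depth_mm`, `window_start_h`,
#'   `window_end_h`, `volume_ml`, `concentration_ug_ml`.
#' @export
sample_solution <- function(solution, probes, schedule,
                            mode = c("window_average", "midpoint"),
                            n_quad = 8) {
  mode <- match.arg(mode)
  stopifnot(inherits(solution, "column_solution"), is.data.frame(probes),
            is.data.frame(schedule))
  if (n_quad %% 2 != 0) abort("`n_quad` must be even (Simpson quadrature).")
  depths <- probes$depth_mm
  if (mode == "midpoint") {
    tm <- (schedule$window_start_h + schedule$window_end_h) / 2
    vals <- .eval_dissolved(solution, depths, tm) # probes x windows
  } else {
    w_simpson <- c(1, rep(c(4, 2), length.out = n_quad - 1), 1)
    vals <- matrix(0, length(depths), nrow(schedule))
    for (j in seq_len(nrow(schedule))) {
      tq <- seq(schedule$window_start_h[j], schedule$window_end_h[j],
                length.out = n_quad + 1)
      fq <- .eval_dissolved(solution, depths, tq)
      vals[, j] <- drop(fq %*% w_simpson) / (3 * n_quad)
    }
  }
  nw <- nrow(schedule)
  tibble(
    probe_id = rep(probes$probe_id, times = nw),
    depth_mm = rep(depths, times = nw),
    window_start_h = rep(schedule$window_start_h, each = length(depths)),
    window_end_h = rep(schedule$window_end_h, each = length(depths)),
    volume_ml = rep(schedule$volume_ml, each = length(depths)),
    concentration_ug_ml = as.vector(vals)
  )
}

#' Device calibration (recovery) model
#'
#' Microdialysis reports only a fraction of the true soil-solution
#' concentration (the relative recovery), and that fraction falls as the
#' concentration rises. This is modelled as a power law:
#' `reported = gain * true^recovery_exponent` with `recovery_exponent <= 1`,
#' so the reported/true ratio is strictly decreasing in concentration when
#' the exponent is below one. The inverse transform is the correction
#' applied to probe data to recover effective soil-solution concentrations.
#' Suction cups withdraw solution directly and default to the identity.
#'
#' @param device `"microdialysis"` or `"suction_cup"`.
#' @param gain Multiplicative recovery gain (> 0).
#' @param recovery_exponent Power-law exponent in (0, 1].
#' @param detection_limit Reporting limit, ug P ml^-1; readings below it are
#'   flagged as censored.
#' @return An object of class `calibration_model`.
#' @export
calibration_model <- function(device = c("microdialysis", "suction_cup"),
                              gain = NULL, recovery_exponent = NULL,
                              detection_limit = 0.01) {
  device <- match.arg(device)
  if (is.null(gain)) gain <- if (device == "microdialysis") 0.5 else 1
  if (is.null(recovery_exponent))
    recovery_exponent <- if (device == "microdialysis") 0.9 else 1
  if (gain <= 0) abort("`gain` must be positive.")
  if (recovery_exponent <= 0 || recovery_exponent > 1)
    abort("`recovery_exponent` must be in (0, 1].")
  if (detection_limit < 0) abort("`detection_limit` must be >= 0.")
  structure(list(device = device, gain = gain,
                 recovery_exponent = recovery_exponent,
                 detection_limit = detection_limit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s: reported = %.3g * true^%.3g, LOD %.3g ug ml^-1\n",
              x$device, x$gain, x$recovery_exponent, x$detection_limit))
  invisible(x)
}

#' Apply the device recovery model
#'
#' Maps true soil-solution concentrations to what the device reports,
#' `gain * true^recovery_exponent`.
#'
#' @param true_conc Non-negative concentrations, ug P ml^-1.
#' @param calib A [calibration_model()].
#' @return Reported concentrations (same length).
#' @seealso [invert_recovery()] for the calibration correction, and
#'   `reported < calib$detection_limit` for censoring.
#' @export
apply_recovery <- function(true_conc, calib) {
  stopifnot(inherits(calib, "calibration_model"))
  if (any(true_conc < 0, na.rm = TRUE))
    abort("Concentrations must be non-negative.")
  calib$gain * true_conc^calib$recovery_exponent
}

#' Invert the device recovery model
#'
#' The calibration correction: maps device-reported concentrations back to
#' effective soil-solution concentrations, the exact inverse of
#' [apply_recovery()]. Censored readings (below the detection limit) stay
#' censored: their corrected value is `NA` unless `keep_censored_values` is
#' set.
#'
#' @param reported Non-negative reported concentrations.
#' @param calib A [calibration_model()].
#' @param censored Optional logical vector marking censored readings.
#' @param keep_censored_values If `TRUE`, censored readings are still
#'   back-transformed instead of set to `NA`.
#' @return Numeric vector of corrected concentrations.
#' @export
invert_recovery <- function(reported, calib, censored = NULL,
                            keep_censored_values = TRUE) {
  stopifnot(inherits(calib, "calibration_model"))
  if (any(reported < 0, na.rm = TRUE))
    abort("Reported concentrations must be non-negative.")
  out <- (reported / calib$gain)^(1 / calib$recovery_exponent)
  if (!is.null(censored) && !keep_censored_values) out[censored] <- NA_real_
  out
}
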