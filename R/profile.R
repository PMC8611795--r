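# integral of the piecewise-linear interpolant of (z, y) over [a, b]
.integrate_linear <- function(z, y, a, b) {
  inner <- z[z > a & z < b]
  zz <- c(a, inner, b)
  yy <- approx(z, y, xout = zz, rule = 2)$y
  sum(diff(zz) * (head(yy, -1) + tail(yy, -1)) / 2)
}

#' Predicted end-of-run total-phosphorus depth profile
#'
#' Emulates the destructive slicing-and-digestion measurement: the column is
#' cut into horizontal slices and each slice's total P content is expressed
#' per gram of dry soil. Model concentrations are per unit pore-solution
#' volume, so a slice's content is
#' `background_total_p + porosity * mean(dissolved + adsorbed) / bulk_density`.
#'
#' @param solution A `column_solution`.
#' @param soil A [soil_spec()].
#' @param slice_thickness Slice thickness in mm (default 5, i.e. 0.5 cm).
#' @param time_index Which stored time to slice (default: the last).
#' @return A tibble with columns `slice_top_mm`, `slice_bottom_mm`,
#'   `total_p_ug_g`.
#' @export
predict_total_p_profile <- function(solution, soil, slice_thickness = 5,
                                    time_index = NULL) {
  stopifnot(inherits(solution, "column_solution"), inherits(soil, "soil_spec"))
  grid <- solution$grid
  if (slice_thickness < grid$h_mm)
    abort(sprintf(
      "Slice thickness %g mm is thinner than the grid spacing %g mm.",
      slice_thickness, grid$h_mm), class = "pelletpulse_config_error")
  if (is.null(time_index)) time_index <- length(solution$times_h)
  if (time_index < 1 || time_index > length(solution$times_h))
    abort("`time_index` out of range.")
  n_slices <- round(grid$length_mm / slice_thickness)
  if (n_slices < 1 ||
      abs(n_slices * slice_thickness - grid$length_mm) > 0.01 * grid$length_mm)
    abort(sprintf(
      "`slice_thickness` (%g mm) must divide the column length (%g mm) approximately.",
      slice_thickness, grid$length_mm), class = "pelletpulse_config_error")
  breaks <- seq(0, grid$length_mm, length.out = n_slices + 1)
  total <- solution$dissolved[, time_index] + solution$adsorbed[, time_index]
  phi <- porosity(soil)
  means <- purrr::map_dbl(seq_len(n_slices), function(i) {
    .integrate_linear(grid$z_mm, total, breaks[i], breaks[i + 1]) /
      (breaks[i + 1] - breaks[i])
  })
  tibble(slice_top_mm = head(breaks, -1),
         slice_bottom_mm = tail(breaks, -1),
         total_p_ug_g = soil$background_total_p +
           phi * means / soil$bulk_density)
}
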