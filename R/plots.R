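#' Plot depth profiles of a column solution
#'
#' Dissolved and adsorbed phosphorus against depth at a selection of stored
#' times, depth increasing downwards as in the column.
#'
#' @param object A `column_solution`.
#' @param times_h Times to display (nearest stored times are used; default:
#'   up to six spread over the run).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot column_solution
#' @export
autoplot.column_solution <- function(object, times_h = NULL, ...) {
  if (is.null(times_h))
    times_h <- object$times_h[unique(round(seq(1, length(object$times_h),
                                               length.out = 6)))]
  idx <- unique(vapply(times_h, function(t)
    which.min(abs(object$times_h - t)), integer(1)))
  df <- tidy(object) %>%
    filter(.data$time_h %in% object$times_h[idx]) %>%
    tidyr::pivot_longer(c("dissolved_ug_ml", "adsorbed_ug_ml"),
                        names_to = "pool", values_to = "conc") %>%
    mutate(pool = ifelse(.data$pool == "dissolved_ug_ml", "dissolved",
                         "adsorbed"))
  ggplot(df, aes(x = .data$conc, y = .data$depth_mm,
                 colour = factor(.data$time_h))) +
    geom_path() +
    facet_wrap(~pool, scales = "free_x") +
    scale_y_reverse() +
    labs(x = "concentration (ug P ml^-1)", y = "depth (mm)",
         colour = "time (h)") +
    theme_minimal()
}

#' Plot a synthetic or measured probe dataset
#'
#' Per-probe time series of the window means with +/- 1 SD ribbons, drawn at
#' the window midpoints.
#'
#' @param dataset A probe dataset tibble (mean/SD layout).
#' @return A ggplot object.
#' @export
plot_probe_dataset <- function(dataset) {
  df <- dataset %>%
    mutate(time_h = (.data$window_start_h + .data$window_end_h) / 2,
           probe = sprintf("%s (%g mm)", .data$probe_id, .data$depth_mm))
  ggplot(df, aes(x = .data$time_h, y = .data$mean_ug_ml)) +
    geom_ribbon(aes(ymin = pmax(.data$mean_ug_ml - .data$sd_ug_ml, 0),
                    ymax = .data$mean_ug_ml + .data$sd_ug_ml),
                fill = "grey80") +
    geom_point(size = 0.8) + geom_line(linewidth = 0.3) +
    facet_wrap(~probe, scales = "free_y") +
    labs(x = "time (h)", y = "dissolved P (ug ml^-1)") +
    theme_minimal()
}

#' Plot observed data against fitted curves
#'
#' The classic fit figure: per-probe observed window means with +/- 1 SD
#' error bars and the fitted model's dissolved-P curve at the probe depth.
#'
#' @param object A `pellet_fit`.
#' @param report Optional precomputed [fit_report()] (avoids re-solving).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pellet_fit
#' @export
autoplot.pellet_fit <- function(object, report = NULL, ...) {
  if (is.null(report)) report <- fit_report(object)
  obs <- object$data %>%
    mutate(time_h = (.data$window_start_h + .data$window_end_h) / 2,
           probe = sprintf("%g mm", .data$depth_mm))
  curves <- report$curves %>%
    mutate(probe = sprintf("%g mm", .data$depth_mm))
  ggplot(obs, aes(x = .data$time_h, y = .data$mean_ug_ml)) +
    geom_errorbar(aes(ymin = pmax(.data$mean_ug_ml - .data$sd_ug_ml, 0),
                      ymax = .data$mean_ug_ml + .data$sd_ug_ml),
                  width = 4, colour = "firebrick") +
    geom_point(colour = "firebrick", size = 0.9) +
    geom_line(data = curves,
              aes(x = .data$time_h, y = .data$dissolved_ug_ml),
              colour = "steelblue") +
    facet_wrap(~probe, scales = "free_y") +
    labs(x = "time (h)", y = "dissolved P (ug ml^-1)") +
    theme_minimal()
}

#' Plot an end-of-run total-phosphorus depth profile
#'
#' @param profile Tibble from [generate_total_p_profile()] (columns
#'   `mean_ug_g`/`sd_ug_g`) or [predict_total_p_profile()]
#'   (`total_p_ug_g`).
#' @return A ggplot object.
#' @export
plot_total_p_profile <- function(profile) {
  df <- profile %>%
    mutate(mid = (.data$slice_top_mm + .data$slice_bottom_mm) / 2)
  if ("mean_ug_g" %in% names(df)) {
    ggplot(df, aes(x = .data$mean_ug_g, y = .data$mid)) +
      geom_errorbarh(aes(xmin = .data$mean_ug_g - .data$sd_ug_g,
                         xmax = .data$mean_ug_g + .data$sd_ug_g),
                     height = 1.5) +
      geom_point() + geom_path() +
      scale_y_reverse() +
      labs(x = "total P (ug g^-1 soil)", y = "depth (mm)") +
      theme_minimal()
  } else {
    ggplot(df, aes(x = .data$total_p_ug_g, y = .data$mid)) +
      geom_point() + geom_path() +
      scale_y_reverse() +
      labs(x = "total P (ug g^-1 soil)", y = "depth (mm)") +
      theme_minimal()
  }
}
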