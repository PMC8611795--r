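.FIT_TERMS <- c("diffusivity", "adsorption_rate", "desorption_rate",
                "peak", "spread_above", "spread_below")

#' Default box bounds for the six fitted parameters
#'
#' Wide physically motivated boxes: diffusivities between free-solution and
#' strongly impeded values, exchange rates spanning minutes to years, pulse
#' peaks up to fertilizer-saturated solution strength, spreads within the
#' column.
#'
#' @return A list with numeric vectors `lower` and `upper` named by term.
#' @export
default_fit_bounds <- function() {
  list(
    lower = c(diffusivity = 1e-13, adsorption_rate = 1e-8,
              desorption_rate = 1e-11, peak = 1,
              spread_above = 0.5, spread_below = 2),
    upper = c(diffusivity = 1e-9, adsorption_rate = 1e-4,
              desorption_rate = 1e-6, peak = 1e4,
              spread_above = 10, spread_below = 25)
  )
}

#' Configuration of the parameter-estimation problem
#'
#' Controls the weighted-least-squares fit of the six model parameters
#' (D, beta1, beta2, pulse peak and spreads). Rates and diffusivity are
#' optimized in log space because plausible values span several orders of
#' magnitude. Only data recorded from `fit_start_time_h` onward enter the
#' objective: the early pulse emission is faster than the model's initial
#' condition can represent, so fitting starts once a steady diffusion
#' pattern has developed. Standard deviations smaller than
#' `sigma_floor * mean` are raised to that floor (the objective is undefined
#' for zero SDs, which occur whenever replicates coincide).
#'
#' @param params_init Initial guess [transport_params()] (defaults: the
#'   optimizer starting values of the coarse-soil study, D = 1.9e-11 m^2/s,
#'   beta1 = 3.1e-6 /s, beta2 = 3.6e-9 /s).
#' @param pulse_init Initial guess [initial_pulse()] (default peak 850
#'   ug/ml, spreads 3/12 mm); its pellet/break depths and adsorbed
#'   background are held fixed.
#' @param bounds List with `lower`/`upper` named vectors, see
#'   [default_fit_bounds()].
#' @param fit_start_time_h Discard windows starting before this time (h).
#' @param sigma_floor Relative SD floor (fraction of the window mean).
#' @param log_scale Terms optimized on the log scale.
#' @param mode Reading mode used for model predictions
#'   (`"window_average"` or `"midpoint"`).
#' @param multistart Number of optimizer starts (default 5: the initial guess
#'   plus four random perturbations within the bounds; the objective has
#'   local minima that a single start can fall into).
#' @param seed Seed for multistart perturbations.
#' @param max_iter,ftol,ptol Levenberg-Marquardt controls.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(params_init = transport_params(1.9e-11, 3.1e-6, 3.6e-9),
                       pulse_init = initial_pulse(peak = 850, spread_above = 3,
                                                  spread_below = 12),
                       bounds = default_fit_bounds(),
                       fit_start_time_h = 8,
                       sigma_floor = 0.05,
                       log_scale = c("diffusivity", "adsorption_rate",
                                     "desorption_rate"),
                       mode = "window_average",
                       multistart = 5, seed = 1,
                       max_iter = 200, ftol = 1e-10, ptol = 1e-8) {
  stopifnot(inherits(params_init, "transport_params"),
            inherits(pulse_init, "initial_pulse"))
  if (fit_start_time_h < 0) abort("`fit_start_time_h` must be >= 0.")
  if (sigma_floor < 0) abort("`sigma_floor` must be >= 0.")
  init <- c(diffusivity = params_init$diffusivity,
            adsorption_rate = params_init$adsorption_rate,
            desorption_rate = params_init$desorption_rate,
            peak = pulse_init$peak,
            spread_above = pulse_init$spread_above,
            spread_below = pulse_init$spread_below)
  if (!all(.FIT_TERMS %in% names(bounds$lower)) ||
      !all(.FIT_TERMS %in% names(bounds$upper)))
    abort("`bounds` must name lower and upper values for all six terms.")
  lo <- bounds$lower[.FIT_TERMS]; up <- bounds$upper[.FIT_TERMS]
  if (any(init < lo | init > up))
    abort(sprintf("Initial guess outside bounds for: %s.",
                  paste(.FIT_TERMS[init < lo | init > up], collapse = ", ")))
  structure(list(params_init = params_init, pulse_init = pulse_init,
                 lower = lo, upper = up,
                 fit_start_time_h = fit_start_time_h,
                 sigma_floor = sigma_floor,
                 log_scale = intersect(log_scale, .FIT_TERMS),
                 mode = mode, multistart = as.integer(multistart),
                 seed = as.integer(seed), max_iter = max_iter,
                 ftol = ftol, ptol = ptol),
            class = "fit_config")
}

# candidate vector -> typed parameter objects (fixed geometry from pulse_init)
.theta_to_objects <- function(theta, pulse_init) {
  list(params = transport_params(theta[["diffusivity"]],
                                 theta[["adsorption_rate"]],
                                 theta[["desorption_rate"]]),
       pulse = initial_pulse(peak = theta[["peak"]],
                             spread_above = theta[["spread_above"]],
                             spread_below = theta[["spread_below"]],
                             pellet_depth = pulse_init$pellet_depth,
                             break_depth = pulse_init$break_depth,
                             adsorbed_background = pulse_init$adsorbed_background))
}

# model readings at the dataset's (depth, window) pairs
.model_readings <- function(params, pulse, grid, rows, mode = "window_average",
                            method = "modal", rtol = 1e-8) {
  key <- function(d, s, e) paste(signif(d, 10), signif(s, 10), signif(e, 10))
  uw <- unique(rows[, c("window_start_h", "window_end_h")])
  probes <- tibble(probe_id = as.character(sort(unique(rows$depth_mm))),
                   depth_mm = sort(unique(rows$depth_mm)),
                   device = "microdialysis", flow_rate_ul_min = 3.3)
  schedule <- tibble(window_start_h = uw$window_start_h,
                     window_end_h = uw$window_end_h, volume_ml = NA_real_)
  out_times <- if (method == "modal") c(0, max(schedule$window_end_h)) else
    schedule_output_times(schedule)
  sol <- solve_transport(params, pulse, grid, output_times_h = out_times,
                         method = method, rtol = rtol)
  pred <- sample_solution(sol, probes, schedule, mode = mode)
  idx <- match(key(rows$depth_mm, rows$window_start_h, rows$window_end_h),
               key(pred$depth_mm, pred$window_start_h, pred$window_end_h))
  pred$concentration_ug_ml[idx]
}

# retained rows + floored SDs
.prepare_dataset <- function(dataset, fit_start_time_h, sigma_floor) {
  req <- c("depth_mm", "window_start_h", "window_end_h", "mean_ug_ml",
           "sd_ug_ml")
  if (!all(req %in% names(dataset)))
    abort(sprintf("Dataset must have columns: %s.", paste(req, collapse = ", ")))
  rows <- dplyr::filter(dataset, .data$window_start_h >= fit_start_time_h)
  if (nrow(rows) == 0)
    abort(sprintf("No observations at or after the fit start time (%g h).",
                  fit_start_time_h), class = "pelletpulse_fit_error")
  rows$sigma <- pmax(rows$sd_ug_ml, sigma_floor * abs(rows$mean_ug_ml),
                     .Machine$double.eps)
  rows
}

#' Weighted least-squares objective of the inverse problem
#'
#' The error functional minimized by the fit: the sum over retained probe
#' observations of squared residuals between the model's dissolved
#' concentration at the probe depth and sampling window and the observed
#' replicate mean, weighted by the inverse replicate variance,
#' \deqn{R = \sum_{i,j} (c_{sol}(l_i, t_j) - \phi_{ij})^2 / \sigma_{ij}^2.}
#'
#' @param dataset Probe dataset tibble (columns `depth_mm`,
#'   `window_start_h`, `window_end_h`, `mean_ug_ml`, `sd_ug_ml`).
#' @param params Candidate [transport_params()].
#' @param pulse Candidate [initial_pulse()].
#' @param grid A [column_grid()].
#' @param fit_start_time_h Discard windows starting before this time (h).
#' @param sigma_floor Relative SD floor.
#' @param mode Reading mode for model predictions.
#' @param method Forward-solver method.
#' @return The scalar objective R (dimensionless).
#' @export
objective_R <- function(dataset, params, pulse, grid = column_grid(),
                        fit_start_time_h = 8, sigma_floor = 0.05,
                        mode = "window_average", method = "modal") {
  rows <- .prepare_dataset(dataset, fit_start_time_h, sigma_floor)
  model <- .model_readings(params, pulse, grid, rows, mode, method)
  sum(((model - rows$mean_ug_ml) / rows$sigma)^2)
}

#' Estimate transport and pulse parameters from probe data
#'
#' Minimizes the weighted least-squares functional of [objective_R()] over
#' the six parameters (effective diffusivity, adsorption and desorption
#' rates, pulse peak and spreads) by bounded Levenberg-Marquardt on the
#' weighted residual vector, with rates and diffusivity log-transformed.
#' Forward solves inside the optimizer use the exact modal evolution of the
#' finite-difference operator; the returned fit is re-evaluated with the
#' stiff time integrator at tight tolerance as an independent confirmation.
#'
#' @param dataset Probe dataset tibble (see [objective_R()]).
#' @param config A [fit_config()].
#' @param grid A [column_grid()].
#' @param refine_method `"lsoda"` (default) re-solves the fitted model with
#'   [deSolve::lsoda()] at `rtol = 1e-8` for the reported predictions;
#'   `"none"` keeps the modal predictions.
#' @return An object of class `pellet_fit`; see [tidy.pellet_fit()] and
#'   [glance.pellet_fit()].
#' @export
fit_parameters <- function(dataset, config = fit_config(),
                           grid = column_grid(),
                           refine_method = c("lsoda", "none")) {
  refine_method <- match.arg(refine_method)
  stopifnot(inherits(config, "fit_config"))
  rows <- .prepare_dataset(dataset, config$fit_start_time_h,
                           config$sigma_floor)
  is_log <- .FIT_TERMS %in% config$log_scale
  fwd <- function(x) ifelse(is_log, log(x), x)
  bwd <- function(u) setNames(ifelse(is_log, exp(u), u), .FIT_TERMS)
  init <- c(diffusivity = config$params_init$diffusivity,
            adsorption_rate = config$params_init$adsorption_rate,
            desorption_rate = config$params_init$desorption_rate,
            peak = config$pulse_init$peak,
            spread_above = config$pulse_init$spread_above,
            spread_below = config$pulse_init$spread_below)
  lo_t <- fwd(config$lower); up_t <- fwd(config$upper)
  n_evals <- 0L
  residual_fun <- function(u) {
    n_evals <<- n_evals + 1L
    cand <- .theta_to_objects(bwd(u), config$pulse_init)
    model <- .model_readings(cand$params, cand$pulse, grid, rows,
                             mode = config$mode, method = "modal")
    (model - rows$mean_ug_ml) / rows$sigma
  }
  starts <- list(fwd(init))
  if (config$multistart > 1) {
    set.seed(config$seed)
    for (k in seq_len(config$multistart - 1)) {
      u <- fwd(init) + stats::runif(length(init), -0.25, 0.25) * (up_t - lo_t)
      starts[[k + 1]] <- pmin(pmax(u, lo_t), up_t)
    }
  }
  fits <- purrr::map(starts, function(u0) {
    tryCatch(
      minpack.lm::nls.lm(par = u0, lower = unname(lo_t), upper = unname(up_t),
                         fn = residual_fun,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$max_iter, ftol = config$ftol,
                           ptol = config$ptol, maxfev = 10000)),
      error = function(e) NULL)
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0)
    abort("No optimizer start converged.", class = "pelletpulse_fit_error")
  best <- fits[[which.min(purrr::map_dbl(fits, "deviance"))]]
  theta <- bwd(best$par)
  est <- .theta_to_objects(theta, config$pulse_init)
  span <- up_t - lo_t
  at_bound <- (best$par - lo_t) < 1e-6 * span | (up_t - best$par) < 1e-6 * span
  if (any(at_bound))
    warn(sprintf("Estimates at a bound: %s.",
                 paste(.FIT_TERMS[at_bound], collapse = ", ")))
  model <- .model_readings(est$params, est$pulse, grid, rows,
                           mode = config$mode,
                           method = if (refine_method == "lsoda") "lsoda"
                                    else "modal",
                           rtol = 1e-8)
  rows$fitted_ug_ml <- model
  rows$residual <- rows$fitted_ug_ml - rows$mean_ug_ml
  objective <- sum((rows$residual / rows$sigma)^2)
  structure(
    list(params = est$params, pulse = est$pulse,
         par_table = tibble(term = .FIT_TERMS,
                            estimate = unname(theta),
                            initial = unname(init),
                            lower = unname(config$lower),
                            upper = unname(config$upper),
                            log_scale = is_log, at_bound = unname(at_bound)),
         objective = objective,
         fit_error_percent = 100 * sqrt(sum(rows$residual^2) /
                                          sum(rows$mean_ug_ml^2)),
         n_obs = nrow(rows), converged = best$info %in% 1:4,
         info = best$info, message = best$message,
         n_function_evals = n_evals, n_iter = best$niter,
         data = rows, config = config, grid = grid,
         refine_method = refine_method),
    class = "pellet_fit"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pellet_fit <- function(x, ...) {
  cat("<pellet_fit>\n")
  cat(sprintf("  objective R = %.4g over %d observations; fit error %.1f%%\n",
              x$objective, x$n_obs, x$fit_error_percent))
  cat(sprintf("  converged: %s (info %d, %d function evaluations)\n",
              x$converged, x$info, x$n_function_evals))
  print(as.data.frame(x$par_table[, c("term", "estimate", "initial",
                                      "at_bound")]), row.names = FALSE)
  invisible(x)
}

#' Tidy a fitted pellet-pulse model
#'
#' @param x A `pellet_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fitted term: `term`, `estimate`,
#'   `initial`, `lower`, `upper`, `log_scale`, `at_bound`.
#' @method tidy pellet_fit
#' @export
tidy.pellet_fit <- function(x, ...) x$par_table

#' One-row fit summary
#'
#' @param x A `pellet_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `objective`, `fit_error_percent`, `n_obs`,
#'   `converged`, `n_function_evals`, `n_iter`.
#' @method glance pellet_fit
#' @export
glance.pellet_fit <- function(x, ...) {
  tibble(objective = x$objective, fit_error_percent = x$fit_error_percent,
         n_obs = x$n_obs, converged = x$converged,
         n_function_evals = x$n_function_evals, n_iter = x$n_iter)
}

#' Percent fit error of a fitted model
#'
#' Summarizes fit quality as a single percentage. The default definition is
#' the normalized root-mean-square error over the retained observations,
#' `100 * sqrt(sum((model - obs)^2) / sum(obs^2))`; a mean absolute
#' percentage error is available as an alternative convention.
#'
#' @param fit A `pellet_fit`.
#' @param definition `"nrmse"` (default) or `"mape"`.
#' @return The fit error in percent.
#' @export
fit_error_percent <- function(fit, definition = c("nrmse", "mape")) {
  definition <- match.arg(definition)
  stopifnot(inherits(fit, "pellet_fit"))
  obs <- fit$data$mean_ug_ml; mod <- fit$data$fitted_ug_ml
  if (all(obs == 0)) abort("Fit error undefined: all observations are zero.")
  if (definition == "nrmse") 100 * sqrt(sum((mod - obs)^2) / sum(obs^2))
  else 100 * mean(abs(mod - obs) / abs(obs))
}

#' Per-probe fit report
#'
#' Bundles everything needed to inspect a fit: the parameter table with
#' bound flags, the observed-vs-fitted table with residuals, and smooth
#' per-probe predicted curves from a high-fidelity re-solve of the fitted
#' model.
#'
#' @param fit A `pellet_fit`.
#' @param curve_times_h Times at which the predicted curves are evaluated.
#' @return A list of class `pellet_fit_report` with elements `parameters`,
#'   `observations`, `curves` and `summary` (character).
#' @export
fit_report <- function(fit, curve_times_h = NULL) {
  stopifnot(inherits(fit, "pellet_fit"))
  if (is.null(curve_times_h))
    curve_times_h <- seq(0, max(fit$data$window_end_h), length.out = 145)
  depths <- sort(unique(fit$data$depth_mm))
  sol <- solve_transport(fit$params, fit$pulse, fit$grid,
                         output_times_h = sort(unique(c(0, curve_times_h))),
                         method = "modal")
  curves <- purrr::map(depths, function(d) {
    tibble(depth_mm = d, time_h = sol$times_h,
           dissolved_ug_ml = drop(.eval_dissolved(sol, d, sol$times_h)))
  }) %>% bind_rows()
  summary_txt <- c(
    sprintf("Fit over %d observations (from %g h): R = %.4g, error = %.1f%%",
            fit$n_obs, fit$config$fit_start_time_h, fit$objective,
            fit$fit_error_percent),
    sprintf("  %-16s %12.4g (initial %.4g)%s", fit$par_table$term,
            fit$par_table$estimate, fit$par_table$initial,
            ifelse(fit$par_table$at_bound, "  [at bound]", "")))
  structure(list(parameters = fit$par_table,
                 observations = fit$data,
                 curves = curves,
                 summary = summary_txt),
            class = "pellet_fit_report")
}

#' @export
print.pellet_fit_report <- function(x, ...) {
  cat(paste(x$summary, collapse = "\n"), "\n")
  invisible(x)
}
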