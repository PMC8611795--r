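test_that("the objective is zero at the generating truth and sums correctly", {
  g <- small_grid()
  tr <- ref_truth()
  gen <- generate_dataset(tr$params, tr$pulse, schedule = short_schedule(),
                          noise = noise_model(0, 0, 3, seed = 1), grid = g)
  expect_lt(objective_R(gen$dataset, tr$params, tr$pulse, g), 1e-12)
  # hand-built residuals: (2/2)^2 + (1/1)^2 = 2
  rows <- gen$dataset[gen$dataset$window_start_h >= 8, ][1:2, ]
  model <- pelletpulse:::.model_readings(tr$params, tr$pulse, g, rows)
  rows$mean_ug_ml <- model - c(2, 1)
  rows$sd_ug_ml <- c(2, 1)
  expect_equal(objective_R(rows, tr$params, tr$pulse, g, sigma_floor = 0), 2,
               tolerance = 1e-8)
  # a single observation with residual exactly sigma scores 1
  one <- rows[1, ]; one$mean_ug_ml <- model[1] - 5; one$sd_ug_ml <- 5
  expect_equal(objective_R(one, tr$params, tr$pulse, g, sigma_floor = 0), 1,
               tolerance = 1e-8)
})

test_that("an empty post-filter dataset is rejected", {
  g <- small_grid()
  tr <- ref_truth()
  gen <- generate_dataset(tr$params, tr$pulse,
                          schedule = build_schedule(total_duration_h = 48),
                          noise = noise_model(0, 0, 3, seed = 1), grid = g)
  early <- gen$dataset[gen$dataset$window_start_h < 8, ]
  expect_error(objective_R(early, tr$params, tr$pulse, g), "fit start")
  expect_error(fit_parameters(early, fit_config(), g), "fit start")
})

test_that("noise-free data are fit essentially exactly from the standard start", {
  g <- column_grid(70, 401)
  tr <- ref_truth()
  gen <- generate_dataset(tr$params, tr$pulse,
                          noise = noise_model(0, 0, 3, seed = 1), grid = g)
  cfg <- fit_config()
  r0 <- objective_R(gen$dataset, cfg$params_init, cfg$pulse_init, g)
  fit <- fit_parameters(gen$dataset, cfg, g, refine_method = "none")
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-4 * r0)
  est <- tidy(fit)$estimate
  expect_equal(est, unname(ref_truth_vector()), tolerance = 1e-4)
  expect_lt(fit_error_percent(fit), 0.1)
})

test_that("the truth is locally optimal against single-parameter perturbations", {
  g <- small_grid()
  tr <- ref_truth()
  gen <- generate_dataset(tr$params, tr$pulse, schedule = short_schedule(),
                          noise = noise_model(0, 0, 3, seed = 1), grid = g)
  r_truth <- objective_R(gen$dataset, tr$params, tr$pulse, g)
  tv <- ref_truth_vector()
  for (term in names(tv)) for (fac in c(0.5, 1.5)) {
    th <- tv; th[term] <- th[term] * fac
    cand <- pelletpulse:::.theta_to_objects(th, tr$pulse)
    expect_gte(objective_R(gen$dataset, cand$params, cand$pulse, g), r_truth)
  }
})

test_that("fitting is invariant to the order of dataset rows", {
  g <- small_grid()
  tr <- ref_truth()
  gen <- generate_dataset(tr$params, tr$pulse, schedule = short_schedule(),
                          noise = noise_model(seed = 21), grid = g)
  f1 <- fit_parameters(gen$dataset, fit_config(), g, refine_method = "none")
  set.seed(99)
  shuffled <- gen$dataset[sample(nrow(gen$dataset)), ]
  f2 <- fit_parameters(shuffled, fit_config(), g, refine_method = "none")
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-6)
})

test_that("recovery error grows with measurement noise", {
  g <- column_grid(70, 401)
  tr <- ref_truth()
  tv <- ref_truth_vector()
  med_err <- function(cv) {
    errs <- sapply(11:13, function(s) {
      gen <- generate_dataset(tr$params, tr$pulse,
                              noise = noise_model(probe_bias_cv = 0,
                                                  measurement_cv = cv,
                                                  seed = s), grid = g)
      f <- fit_parameters(gen$dataset, fit_config(), g,
                          refine_method = "none")
      median(abs(tidy(f)$estimate - tv) / tv)
    })
    median(errs)
  }
  errs <- vapply(c(0, 0.06, 0.24), med_err, numeric(1))
  expect_true(all(diff(errs) > -0.005))
  expect_lt(errs[1], 1e-6)
})

test_that("fit error definitions behave as declared", {
  fake <- structure(list(data = tibble::tibble(
    mean_ug_ml = c(10, 5, 2), fitted_ug_ml = 1.22 * c(10, 5, 2))),
    class = "pellet_fit")
  expect_equal(fit_error_percent(fake), 22, tolerance = 1e-10)
  expect_equal(fit_error_percent(fake, "mape"), 22, tolerance = 1e-10)
  perfect <- structure(list(data = tibble::tibble(
    mean_ug_ml = c(10, 5), fitted_ug_ml = c(10, 5))), class = "pellet_fit")
  expect_equal(fit_error_percent(perfect), 0)
  zero <- structure(list(data = tibble::tibble(
    mean_ug_ml = c(0, 0), fitted_ug_ml = c(1, 1))), class = "pellet_fit")
  expect_error(fit_error_percent(zero), "zero")
})

test_that("fit reports carry near-zero residuals for noise-free fits", {
  g <- small_grid()
  tr <- ref_truth()
  gen <- generate_dataset(tr$params, tr$pulse, schedule = short_schedule(),
                          noise = noise_model(0, 0, 3, seed = 1), grid = g)
  fit <- fit_parameters(gen$dataset, fit_config(), g, refine_method = "none")
  rep <- fit_report(fit)
  expect_lt(max(abs(rep$observations$residual)), 1e-4)
  expect_true(all(c("parameters", "observations", "curves", "summary") %in%
                    names(rep)))
  expect_equal(sort(unique(rep$curves$depth_mm)), c(10, 30, 45))
  # residual unbiasedness on seeded noisy data
  gen2 <- generate_dataset(tr$params, tr$pulse, schedule = short_schedule(),
                           noise = noise_model(seed = 31), grid = g)
  fit2 <- fit_parameters(gen2$dataset, fit_config(), g,
                         refine_method = "none")
  z <- fit2$data$residual / fit2$data$sigma
  expect_lt(abs(mean(z)), 0.5)
})

test_that("tidy and glance summarize fits in broom style", {
  g <- small_grid()
  tr <- ref_truth()
  gen <- generate_dataset(tr$params, tr$pulse, schedule = short_schedule(),
                          noise = noise_model(0, 0, 3, seed = 1), grid = g)
  fit <- fit_parameters(gen$dataset, fit_config(), g, refine_method = "none")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term, c("diffusivity", "adsorption_rate",
                          "desorption_rate", "peak", "spread_above",
                          "spread_below"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("objective", "fit_error_percent", "n_obs",
                    "converged") %in% names(gl)))
})
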