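test_that("a noise-free generator returns the sampled model values exactly", {
  g <- small_grid()
  tr <- ref_truth()
  gen <- generate_dataset(tr$params, tr$pulse, probe_set(),
                          short_schedule(), calibration_model(),
                          noise_model(0, 0, 3, seed = 7), grid = g)
  sol <- solve_transport(tr$params, tr$pulse, g,
                         pelletpulse:::schedule_output_times(short_schedule()),
                         method = "modal")
  truth <- sample_solution(sol, probe_set(), short_schedule())
  joined <- dplyr::left_join(
    gen$dataset, truth,
    by = c("probe_id", "depth_mm", "window_start_h", "window_end_h"))
  expect_equal(joined$mean_ug_ml, joined$concentration_ug_ml,
               tolerance = 1e-10)
  expect_equal(unique(gen$dataset$sd_ug_ml), 0)
})

test_that("generation is deterministic under a seed and varies across seeds", {
  g <- small_grid()
  tr <- ref_truth()
  a <- generate_dataset(tr$params, tr$pulse, schedule = short_schedule(),
                        noise = noise_model(seed = 42), grid = g)
  b <- generate_dataset(tr$params, tr$pulse, schedule = short_schedule(),
                        noise = noise_model(seed = 42), grid = g)
  c <- generate_dataset(tr$params, tr$pulse, schedule = short_schedule(),
                        noise = noise_model(seed = 43), grid = g)
  expect_identical(a$dataset, b$dataset)
  expect_gt(max(abs(a$dataset$mean_ug_ml - c$dataset$mean_ug_ml)), 0)
})

test_that("the probe bias produces the declared replicate-level CV", {
  g <- small_grid()
  tr <- ref_truth()
  gen <- generate_dataset(tr$params, tr$pulse, probe_set(),
                          build_schedule(total_duration_h = 48),
                          calibration_model("suction_cup"), # identity
                          noise_model(probe_bias_cv = 0.06,
                                      measurement_cv = 0,
                                      n_replicates = 1000, seed = 11),
                          grid = g)
  cvs <- gen$dataset$sd_ug_ml / gen$dataset$mean_ug_ml
  expect_true(all(abs(cvs - 0.06) < 0.005))
  # law of large numbers: replicate mean within 3 SE of the noise-free value
  gen0 <- suppressWarnings(
    generate_dataset(tr$params, tr$pulse, probe_set(),
                     build_schedule(total_duration_h = 48),
                     calibration_model("suction_cup"),
                     noise_model(0, 0, 1, seed = 1), grid = g))
  se <- gen$dataset$sd_ug_ml / sqrt(1000)
  expect_true(all(abs(gen$dataset$mean_ug_ml - gen0$dataset$mean_ug_ml) <
                    3.5 * se))
})

test_that("replicate SDs scale linearly with the mean (multiplicative noise)", {
  g <- small_grid()
  tr <- ref_truth()
  gen <- generate_dataset(tr$params, tr$pulse, probe_set(),
                          short_schedule(),
                          calibration_model("suction_cup"),
                          noise_model(probe_bias_cv = 0.06,
                                      measurement_cv = 0.02,
                                      n_replicates = 300, seed = 5),
                          grid = g)
  d <- gen$dataset
  slope <- sum(d$sd_ug_ml * d$mean_ug_ml) / sum(d$mean_ug_ml^2)
  # regression through the origin recovers the combined CV
  expect_equal(slope, sqrt(0.06^2 + 0.02^2), tolerance = 0.25)
  resid <- d$sd_ug_ml - slope * d$mean_ug_ml
  expect_lt(sd(resid) / mean(d$sd_ug_ml), 0.5)
})

test_that("a single replicate yields zero SDs with a warning", {
  g <- small_grid()
  tr <- ref_truth()
  expect_warning(
    gen <- generate_dataset(tr$params, tr$pulse, schedule = short_schedule(),
                            noise = noise_model(n_replicates = 1, seed = 2),
                            grid = g),
    "sigma floor")
  expect_equal(unique(gen$dataset$sd_ug_ml), 0)
})

test_that("blank columns censor at the detection limit", {
  sch <- short_schedule()
  blank <- generate_blank_dataset(probe_set(), sch,
                                  calibration_model(detection_limit = 0.05),
                                  noise_model(seed = 3))
  expect_equal(unique(blank$dataset$frac_censored), 1)
  expect_equal(unique(blank$dataset$mean_ug_ml), 0)
  blank0 <- generate_blank_dataset(probe_set(), sch,
                                   calibration_model(detection_limit = 0),
                                   noise_model(seed = 3))
  expect_equal(unique(blank0$dataset$frac_censored), 0)
  expect_equal(unique(blank0$dataset$mean_ug_ml), 0)
})

test_that("censoring of a faint background matches a direct Monte Carlo", {
  cal <- calibration_model("suction_cup", detection_limit = 0.02)
  nz <- noise_model(probe_bias_cv = 0, measurement_cv = 0.3,
                    n_replicates = 800, seed = 9)
  blank <- generate_blank_dataset(probe_set()[1, ],
                                  tibble::tibble(window_start_h = 0,
                                                 window_end_h = 2,
                                                 volume_ml = 0.396),
                                  cal, nz, background_ug_ml = 0.02)
  observed <- blank$dataset$frac_censored
  # independent oracle: P(0.02 * lognormal(cv = 0.3) < 0.02)
  set.seed(101)
  sdlog <- sqrt(log(1 + 0.3^2))
  oracle <- mean(0.02 * rlnorm(2e5, -sdlog^2 / 2, sdlog) < 0.02)
  expect_equal(observed, oracle, tolerance = 0.1)
})

test_that("the synthetic digestion profile matches the model when noise-free", {
  g <- small_grid()
  tr <- ref_truth()
  soil <- soil_spec(1.02, 2.65, 597)
  prof <- generate_total_p_profile(tr$params, tr$pulse, soil,
                                   noise = noise_model(0, 0, 3, seed = 1),
                                   grid = g, end_time_h = 336)
  sol <- solve_transport(tr$params, tr$pulse, g, c(0, 336), method = "modal")
  expected <- predict_total_p_profile(sol, soil)
  expect_equal(prof$mean_ug_g, expected$total_p_ug_g, tolerance = 1e-10)
  expect_equal(unique(prof$sd_ug_g), 0)
  # with the reference parameters the peak slice contains the pellet
  top <- prof$slice_top_mm[which.max(prof$mean_ug_g)]
  bottom <- prof$slice_bottom_mm[which.max(prof$mean_ug_g)]
  expect_true(top <= 15 && 15 <= bottom)
})
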