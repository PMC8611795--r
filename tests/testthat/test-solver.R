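test_that("with no diffusion and no exchange the fields are frozen", {
  g <- small_grid()
  for (method in c("lsoda", "modal")) {
    sol <- solve_transport(transport_params(0, 0, 0), initial_pulse(), g,
                           c(0, 24, 336), method = method)
    expect_equal(sol$dissolved[, 2], sol$dissolved[, 1], tolerance = 1e-10)
    expect_equal(sol$dissolved[, 3], sol$dissolved[, 1], tolerance = 1e-10)
    expect_equal(sol$adsorbed[, 3], sol$adsorbed[, 1], tolerance = 1e-10)
  }
})

test_that("with D = 0 every node follows the 2x2 exchange matrix exponential", {
  g <- small_grid()
  b1 <- 2.7e-6; b2 <- 5.2e-7 # test-scaled desorption so both terms matter
  pu <- initial_pulse(900, 3, 12, adsorbed_background = 40)
  times <- c(0, 48, 336)
  ic <- build_initial_condition(pu, g)
  # independent oracle: eigendecomposition of the exchange matrix per node
  M <- matrix(c(-b1, b1, b2, -b2), 2, 2)
  eg <- eigen(M)
  expm_t <- function(t_s) eg$vectors %*% diag(exp(eg$values * t_s)) %*%
    solve(eg$vectors)
  for (method in c("lsoda", "modal")) {
    sol <- solve_transport(transport_params(0, b1, b2), pu, g, times,
                           method = method)
    for (j in 2:3) {
      E <- expm_t(times[j] * 3600)
      expect_equal(sol$dissolved[, j],
                   E[1, 1] * ic$dissolved + E[1, 2] * ic$adsorbed,
                   tolerance = 1e-8)
      expect_equal(sol$adsorbed[, j],
                   E[2, 1] * ic$dissolved + E[2, 2] * ic$adsorbed,
                   tolerance = 1e-8)
    }
  }
})

test_that("total phosphorus is conserved to 1e-6 over the full two weeks", {
  g <- column_grid(70, 401)
  for (method in c("lsoda", "modal")) {
    sol <- solve_transport(transport_params(), initial_pulse(), g,
                           c(0, seq(24, 336, 24)), method = method)
    m <- total_mass(sol)
    expect_lt(max(abs(m - m[1])) / m[1], 1e-6)
  }
})

test_that("finite differences agree with the cosine-spectral oracle", {
  g <- column_grid(70, 401)
  pu <- initial_pulse()
  times <- c(0, 8, 48, 168, 336)
  ic <- build_initial_condition(pu, g)
  fd <- solve_transport(transport_params(), pu, g, times, method = "lsoda")
  sp <- spectral_reference(transport_params(), ic$dissolved, ic$adsorbed,
                           g, times)
  expect_lt(max(abs(fd$dissolved - sp$dissolved)) / max(abs(fd$dissolved)),
            1e-3)
  expect_lt(max(abs(fd$adsorbed - sp$adsorbed)) /
              max(abs(fd$adsorbed[, -1])), 1e-3)
})

test_that("a pure cosine mode decays at its spectral rate", {
  g <- small_grid()
  D <- 1e-9
  L_m <- 70 / 1000
  f0 <- cos(pi * g$z_mm / 70)
  sp <- spectral_reference(transport_params(D, 0, 0), f0,
                           rep(0, g$n_nodes), g, c(0, 6, 24))
  for (j in 2:3) {
    decay <- exp(-D * (pi / L_m)^2 * sp$times_h[j] * 3600)
    expect_equal(sp$dissolved[, j], f0 * decay, tolerance = 1e-10)
  }
  # zero-frequency mode with no exchange is constant in time
  sp0 <- spectral_reference(transport_params(D, 0, 0), rep(7, g$n_nodes),
                            rep(0, g$n_nodes), g, c(0, 24))
  expect_equal(sp0$dissolved[, 2], rep(7, g$n_nodes), tolerance = 1e-12)
})

test_that("pure diffusion of a compact pulse matches the image-sum heat kernel", {
  g <- column_grid(70, 401)
  D <- 1e-9
  pu <- compact_pulse(3)
  sol <- solve_transport(transport_params(D, 0, 0), pu, g, c(0, 2),
                         method = "lsoda")
  a <- 3e-3; zp <- 15e-3; L <- 70e-3
  s2 <- a^2 + 2 * D * 7200
  z <- g$z_mm / 1000
  oracle <- 0
  for (k in -4:4) for (sgn in c(1, -1))
    oracle <- oracle + 900 * a / sqrt(s2) *
      exp(-(z - (sgn * zp + 2 * k * L))^2 / (2 * s2))
  expect_lt(max(abs(sol$dissolved[, 2] - oracle)) / max(oracle), 1e-3)
})

test_that("solutions stay non-negative up to a tiny numerical tolerance", {
  g <- column_grid(70, 401)
  for (method in c("lsoda", "modal")) {
    sol <- solve_transport(transport_params(), initial_pulse(), g,
                           c(0, 1, 12, 100, 336), method = method)
    expect_gt(min(sol$dissolved), -1e-9 * 900)
    expect_gt(min(sol$adsorbed), -1e-9 * 900)
  }
})

test_that("a compact pulse arrives later and weaker at more distant depths", {
  g <- column_grid(70, 401)
  sol <- solve_transport(transport_params(), compact_pulse(3), g, c(0, 336),
                         method = "modal")
  tt <- seq(0.5, 336, 0.5)
  depths <- c(20, 25, 30, 35)
  pv <- sapply(seq_along(depths), function(i)
    drop(sol$evaluator(depths[i], tt)))
  peak_time <- tt[apply(pv, 2, which.max)]
  peak_mag <- apply(pv, 2, max)
  expect_true(all(diff(peak_time) >= 0))
  expect_true(all(diff(peak_mag) <= 0))
})

test_that("the solution relaxes to the exchange-equilibrium state", {
  g <- small_grid()
  p <- transport_params(1e-9, 1e-5, 1e-5)
  sol <- solve_transport(p, initial_pulse(), g, c(0, 5e4), method = "modal")
  eq <- equilibrium_state(p, total_mass(sol)[[1]], g)
  expect_equal(sol$dissolved[, 2], eq$dissolved, tolerance = 1e-8)
  expect_equal(sol$adsorbed[, 2], eq$adsorbed, tolerance = 1e-8)
})

test_that("invalid inputs are rejected", {
  g <- small_grid()
  expect_error(transport_params(-1e-11, 0, 0), "non-negative")
  expect_error(solve_transport(transport_params(), initial_pulse(), g,
                               c(1, 2)), "start at 0")
  expect_error(solve_transport(transport_params(), initial_pulse(), g,
                               c(0, 2, 2)), "ascending")
})
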