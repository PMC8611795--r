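#' @keywords internal
new_column_solution <- function(grid, times_h, dissolved, adsorbed,
                                method = "custom", evaluator = NULL) {
  stopifnot(inherits(grid, "column_grid"),
            nrow(dissolved) == grid$n_nodes,
            ncol(dissolved) == length(times_h),
            all(dim(adsorbed) == dim(dissolved)))
  structure(
    list(grid = grid, times_h = as.numeric(times_h),
         dissolved = dissolved, adsorbed = adsorbed,
         method = method, evaluator = evaluator),
    class = "column_solution"
  )
}

#' @export
print.column_solution <- function(x, ...) {
  cat(sprintf("<column_solution> %d nodes x %d times (0-%g h), method '%s'\n",
              x$grid$n_nodes, length(x$times_h), max(x$times_h), x$method))
  cat(sprintf("  dissolved range: %.4g .. %.4g ug ml^-1\n",
              min(x$dissolved), max(x$dissolved)))
  invisible(x)
}

#' Tidy a column solution into long format
#'
#' @param x A `column_solution`.
#' @param ... Unused.
#' @return A tibble with columns `time_h`, `depth_mm`, `dissolved_ug_ml`,
#'   `adsorbed_ug_ml`.
#' @method tidy column_solution
#' @export
tidy.column_solution <- function(x, ...) {
  tibble(
    time_h = rep(x$times_h, each = x$grid$n_nodes),
    depth_mm = rep(x$grid$z_mm, times = length(x$times_h)),
    dissolved_ug_ml = as.vector(x$dissolved),
    adsorbed_ug_ml = as.vector(x$adsorbed)
  )
}

#' @method as_tibble column_solution
#' @export
as_tibble.column_solution <- function(x, ...) tidy.column_solution(x, ...)

# ---- cosine (DCT-I) machinery shared by the modal and spectral solvers ----

# synthesis matrix C[j, k] = cos((j-1)(k-1) pi / (N-1)); its columns are the
# eigenvectors of the reflected-ghost Neumann Laplacian on a uniform grid.
.cos_basis <- function(n_nodes) {
  j <- seq_len(n_nodes) - 1
  outer(j, j, function(a, b) cos(a * b * pi / (n_nodes - 1)))
}

# analysis matrix A with coefs = A %*% f, inverse of .cos_basis under
# trapezoid weighting (DCT-I orthogonality).
.cos_analysis <- function(n_nodes) {
  C <- .cos_basis(n_nodes)
  w <- rep(1, n_nodes); w[c(1, n_nodes)] <- 0.5
  norm2 <- rep((n_nodes - 1) / 2, n_nodes)
  norm2[c(1, n_nodes)] <- n_nodes - 1
  t(C * w) / norm2
}

# exp(t M_k) for the per-mode 2x2 system d/dt (s,a) = M_k (s,a),
# M_k = [[mu_k - b1, b2], [b1, -b2]]; vectorized over modes and times.
# Returns fields S, A (K x T) given initial mode amplitudes s0, a0.
.evolve_modes <- function(mu, b1, b2, s0, a0, t_s) {
  m11 <- mu - b1; m12 <- b2; m21 <- b1; m22 <- -b2
  tr <- m11 + m22
  det <- m11 * m22 - m12 * m21       # = -mu * b2 >= 0
  disc <- pmax(tr^2 - 4 * det, 0)    # provably >= 0 for mu <= 0, b1 b2 >= 0
  sq <- sqrt(disc)
  r1 <- (tr + sq) / 2; r2 <- (tr - sq) / 2
  e1 <- exp(outer(r1, t_s)); e2 <- exp(outer(r2, t_s))
  den <- r1 - r2
  deg <- den <= .Machine$double.eps * pmax(abs(r1) + abs(r2), 1)
  den[deg] <- 1  # handled below
  E11 <- (e1 * (m11 - r2) - e2 * (m11 - r1)) / den
  E12 <- m12 * (e1 - e2) / den
  E21 <- m21 * (e1 - e2) / den
  E22 <- (e1 * (m22 - r2) - e2 * (m22 - r1)) / den
  if (any(deg)) {
    # repeated eigenvalue: exp(tM) = e^{rt} (I + t (M - r I))
    tmat <- matrix(t_s, nrow = sum(deg), ncol = length(t_s), byrow = TRUE)
    er <- exp(outer(r1[deg], t_s))
    E11[deg, ] <- er * (1 + tmat * (m11[deg] - r1[deg]))
    E12[deg, ] <- er * tmat * m12
    E21[deg, ] <- er * tmat * m21
    E22[deg, ] <- er * tmat * (m22 - r1[deg])
  }
  list(S = E11 * s0 + E12 * a0, A = E21 * s0 + E22 * a0)
}

# shared linear-solution builder: eigenvalues either of the discrete
# (finite-difference) Laplacian or the continuous operator.
.linear_solution <- function(params, dissolved0, adsorbed0, grid, times_h,
                             eigenvalues = c("fd", "exact"), n_modes = NULL,
                             method_label = "modal") {
  eigenvalues <- match.arg(eigenvalues)
  N <- grid$n_nodes
  if (is.null(n_modes)) n_modes <- N
  n_modes <- min(n_modes, N)
  D <- params$diffusivity
  b1 <- params$adsorption_rate; b2 <- params$desorption_rate
  L_m <- mm_to_m(grid$length_mm)
  h_m <- mm_to_m(grid$h_mm)
  k <- seq_len(n_modes) - 1
  mu <- if (eigenvalues == "fd") {
    -(4 * D / h_m^2) * sin(k * pi / (2 * (N - 1)))^2
  } else {
    -D * (k * pi / L_m)^2
  }
  A <- .cos_analysis(N)[seq_len(n_modes), , drop = FALSE]
  C <- .cos_basis(N)[, seq_len(n_modes), drop = FALSE]
  s0 <- drop(A %*% dissolved0)
  a0 <- drop(A %*% adsorbed0)
  t_s <- h_to_s(times_h)
  ev <- .evolve_modes(mu, b1, b2, s0, a0, t_s)
  evaluator <- function(depths_mm, eval_times_h) {
    # cosine modes extend off-node: exact evaluation at arbitrary (z, t)
    Cz <- outer(depths_mm / grid$length_mm, k, function(z, kk) cos(kk * pi * z))
    evt <- .evolve_modes(mu, b1, b2, s0, a0, h_to_s(eval_times_h))
    Cz %*% evt$S
  }
  new_column_solution(grid, times_h, C %*% ev$S, C %*% ev$A,
                      method = method_label, evaluator = evaluator)
}

# ---- public solvers ----

#' Solve the coupled dissolved/adsorbed phosphorus transport equations
#'
#' Integrates, on a 1-D saturated soil column with no-flux (zero-gradient)
#' boundaries at both ends,
#' \deqn{\partial_t c_{sol} = D \partial_z^2 c_{sol} - \beta_1 c_{sol} + \beta_2 c_{ad}}
#' \deqn{\partial_t c_{ad} = \beta_1 c_{sol} - \beta_2 c_{ad}}
#' starting from the piecewise-Gaussian dissolved pulse and uniform adsorbed
#' background described by `pulse`. The exchange term is implemented in the
#' mass-conserving form, so the depth integral of `dissolved + adsorbed` is a
#' constant of the motion.
#'
#' Two methods are available. `"lsoda"` (default) discretizes the Laplacian
#' with second-order central differences and reflected ghost nodes and
#' integrates the stiff method-of-lines system with [deSolve::lsoda()].
#' `"modal"` expands the same finite-difference operator in its cosine
#' eigenmodes and evolves each mode by an exact 2x2 matrix exponential: no
#' time-stepping error, and the returned object can be evaluated at arbitrary
#' times and depths. The two agree to the integrator tolerance.
#'
#' @param params A [transport_params()].
#' @param pulse An [initial_pulse()].
#' @param grid A [column_grid()].
#' @param output_times_h Ascending output times in hours, starting at 0.
#' @param method `"lsoda"` or `"modal"`.
#' @param rtol,atol Integrator tolerances (lsoda only).
#' @return A `column_solution` with fields `grid`, `times_h`, `dissolved` and
#'   `adsorbed` (node x time matrices, ug P ml^-1).
#' @examples
#' sol <- solve_transport(transport_params(), initial_pulse(),
#'                        column_grid(70, 101), c(0, 24, 48), method = "modal")
#' total_mass(sol)
#' @export
solve_transport <- function(params, pulse, grid,
                            output_times_h = c(0, seq(2, 12, 2), seq(24, 336, 24)),
                            method = c("lsoda", "modal"),
                            rtol = 1e-8, atol = 1e-10) {
  method <- match.arg(method)
  stopifnot(inherits(params, "transport_params"),
            inherits(pulse, "initial_pulse"),
            inherits(grid, "column_grid"))
  times <- as.numeric(output_times_h)
  if (length(times) < 1 || times[1] != 0 || is.unsorted(times, strictly = TRUE))
    abort("`output_times_h` must be strictly ascending and start at 0.")
  ic <- build_initial_condition(pulse, grid)
  if (method == "modal") {
    return(.linear_solution(params, ic$dissolved, ic$adsorbed, grid, times,
                            eigenvalues = "fd", method_label = "modal"))
  }
  .solve_lsoda(params, ic$dissolved, ic$adsorbed, grid, times, rtol, atol)
}

#' @keywords internal
.solve_lsoda <- function(params, dissolved0, adsorbed0, grid, times_h,
                         rtol, atol) {
  N <- grid$n_nodes
  h_m <- mm_to_m(grid$h_mm)
  D <- params$diffusivity
  b1 <- params$adsorption_rate; b2 <- params$desorption_rate
  idx_sol <- seq(1, 2 * N, by = 2)
  idx_ad <- seq(2, 2 * N, by = 2)
  y0 <- numeric(2 * N)
  y0[idx_sol] <- dissolved0
  y0[idx_ad] <- adsorbed0
  Dh2 <- D / h_m^2
  rhs <- function(t, y, p) {
    sol <- y[idx_sol]; ad <- y[idx_ad]
    lap <- c(2 * (sol[2] - sol[1]),
             sol[1:(N - 2)] - 2 * sol[2:(N - 1)] + sol[3:N],
             2 * (sol[N - 1] - sol[N]))
    dy <- numeric(2 * N)
    dy[idx_sol] <- Dh2 * lap - b1 * sol + b2 * ad
    dy[idx_ad] <- b1 * sol - b2 * ad
    list(dy)
  }
  out <- deSolve::lsoda(y0, h_to_s(times_h), rhs, parms = NULL,
                        rtol = rtol, atol = atol,
                        jactype = "bandint", bandup = 2, banddown = 2,
                        maxsteps = 500000)
  diag <- attr(out, "istate")
  if (is.null(diag) || diag[1] < 0 || nrow(out) < length(times_h))
    abort(sprintf("Stiff integrator failed (istate = %s) after %d of %d output times.",
                  ifelse(is.null(diag), NA, diag[1]), nrow(out), length(times_h)),
          class = "pelletpulse_solver_error")
  y <- t(unname(out[, -1, drop = FALSE]))
  new_column_solution(grid, times_h,
                      dissolved = y[idx_sol, , drop = FALSE],
                      adsorbed = y[idx_ad, , drop = FALSE],
                      method = "lsoda")
}

#' Cosine-spectral reference solution
#'
#' Independent verification oracle for [solve_transport()]: expands the
#' initial fields in the continuous cosine eigenfunctions
#' \eqn{\cos(k \pi z / L)} of the Neumann Laplacian and evolves each mode by
#' the exact 2x2 matrix exponential of the diffusion-exchange system. Exact up
#' to truncation of the cosine series and quadrature of the initial
#' projection.
#'
#' @param params A [transport_params()].
#' @param dissolved0,adsorbed0 Initial fields sampled at the grid nodes
#'   (ug P ml^-1).
#' @param grid A [column_grid()].
#' @param times_h Ascending output times in hours, starting at 0.
#' @param n_modes Number of cosine modes retained (default: all `n_nodes`).
#' @return A `column_solution`.
#' @export
spectral_reference <- function(params, dissolved0, adsorbed0, grid, times_h,
                               n_modes = NULL) {
  stopifnot(inherits(params, "transport_params"), inherits(grid, "column_grid"),
            length(dissolved0) == grid$n_nodes,
            length(adsorbed0) == grid$n_nodes)
  times <- as.numeric(times_h)
  if (length(times) < 1 || times[1] != 0 || is.unsorted(times, strictly = TRUE))
    abort("`times_h` must be strictly ascending and start at 0.")
  .linear_solution(params, dissolved0, adsorbed0, grid, times,
                   eigenvalues = "exact", n_modes = n_modes,
                   method_label = "spectral")
}

#' Total phosphorus inventory of the column
#'
#' Trapezoidal depth integral of `dissolved + adsorbed`. Because the model
#' loses no phosphorus through the no-flux boundaries, this is constant in
#' time for any valid solution.
#'
#' @param solution A `column_solution`.
#' @param time_index Indices into `solution$times_h` (default: all).
#' @return Named numeric vector of inventories, ug P ml^-1 mm (per unit
#'   cross-sectional area; divide by 100 for ug P mm^-2).
#' @export
total_mass <- function(solution, time_index = NULL) {
  stopifnot(inherits(solution, "column_solution"))
  nt <- length(solution$times_h)
  if (is.null(time_index)) time_index <- seq_len(nt)
  if (any(time_index < 1 | time_index > nt))
    abort(sprintf("`time_index` out of range 1..%d.", nt))
  w <- rep(solution$grid$h_mm, solution$grid$n_nodes)
  w[c(1, solution$grid$n_nodes)] <- solution$grid$h_mm / 2
  tot <- solution$dissolved[, time_index, drop = FALSE] +
    solution$adsorbed[, time_index, drop = FALSE]
  setNames(drop(crossprod(w, tot)), solution$times_h[time_index])
}

#' Long-time equilibrium of the exchange system
#'
#' As t grows the column homogenizes and the dissolved/adsorbed pools settle
#' into the first-order exchange equilibrium: uniform
#' `dissolved* = M / (L (1 + beta1/beta2))` and
#' `adsorbed* = (beta1/beta2) dissolved*`, where M is the conserved total
#' inventory. With `desorption_rate = 0` all phosphorus eventually adsorbs.
#'
#' @param params A [transport_params()].
#' @param initial_mass Conserved inventory M as returned by [total_mass()]
#'   (ug P ml^-1 mm).
#' @param grid A [column_grid()].
#' @return A tibble with columns `depth_mm`, `dissolved`, `adsorbed`.
#' @export
equilibrium_state <- function(params, initial_mass, grid) {
  stopifnot(inherits(params, "transport_params"), inherits(grid, "column_grid"))
  b1 <- params$adsorption_rate; b2 <- params$desorption_rate
  mean_total <- initial_mass / grid$length_mm
  if (b2 == 0) {
    dis <- if (b1 > 0) 0 else mean_total
    ads <- mean_total - dis
  } else {
    dis <- mean_total / (1 + b1 / b2)
    ads <- (b1 / b2) * dis
  }
  tibble(depth_mm = grid$z_mm,
         dissolved = rep(dis, grid$n_nodes),
         adsorbed = rep(ads, grid$n_nodes))
}
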