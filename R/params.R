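#' Transport parameters of the diffusion-adsorption model
#'
#' The dissolved pool diffuses with effective diffusivity D (geometric
#' impedance included, sorption buffering excluded) and exchanges with the
#' adsorbed pool by first-order kinetics: adsorption at rate beta1, desorption
#' at rate beta2. Defaults are the package's reference coarse-soil estimates.
#'
#' @param diffusivity Effective diffusivity D, m^2 s^-1.
#' @param adsorption_rate First-order adsorption rate beta1, s^-1.
#' @param desorption_rate First-order desorption rate beta2, s^-1.
#' @return An object of class `transport_params`.
#' @examples
#' transport_params() # reference coarse-soil values
#' @export
transport_params <- function(diffusivity = 1.6e-11,
                             adsorption_rate = 2.7e-6,
                             desorption_rate = 5.2e-9) {
  vals <- c(diffusivity = diffusivity, adsorption_rate = adsorption_rate,
            desorption_rate = desorption_rate)
  if (!all(is.finite(vals)))
    abort("All transport parameters must be finite numbers.")
  if (any(vals < 0))
    abort("Transport parameters must be non-negative (D, beta1, beta2 >= 0).")
  structure(as.list(vals), class = "transport_params")
}

#' @export
print.transport_params <- function(x, ...) {
  cat("<transport_params>\n")
  cat(sprintf("  D     = %.3g m^2 s^-1\n", x$diffusivity))
  cat(sprintf("  beta1 = %.3g s^-1\n", x$adsorption_rate))
  cat(sprintf("  beta2 = %.3g s^-1\n", x$desorption_rate))
  invisible(x)
}

#' Piecewise-Gaussian initial pulse of dissolved phosphorus
#'
#' Describes the effective dissolved-P distribution shortly after pellet
#' wetting: a Gaussian peak of height `peak` centred at the pellet, with
#' standard deviation `spread_above` above the pellet and `spread_below`
#' below it down to `break_depth`, and a constant tail below the break fixed
#' by continuity. The adsorbed pool starts at a uniform pre-fertilization
#' background.
#'
#' @param peak Peak dissolved concentration at the pellet, ug P ml^-1.
#' @param spread_above Gaussian standard deviation above the pellet, mm.
#' @param spread_below Gaussian standard deviation below the pellet, mm.
#' @param pellet_depth Depth of the pellet centre below the soil surface, mm.
#' @param break_depth Depth (column coordinate, mm) below which the initial
#'   dissolved profile is constant.
#' @param adsorbed_background Uniform initial adsorbed concentration,
#'   ug P ml^-1 (default 0: only departures from the pre-fertilization
#'   equilibrium are observable in probe data).
#' @return An object of class `initial_pulse`.
#' @examples
#' initial_pulse() # reference coarse-soil pulse
#' @export
initial_pulse <- function(peak = 900, spread_above = 3, spread_below = 12,
                          pellet_depth = 15, break_depth = 27.5,
                          adsorbed_background = 0) {
  vals <- c(peak, spread_above, spread_below, pellet_depth, break_depth,
            adsorbed_background)
  if (!all(is.finite(vals)))
    abort("All pulse parameters must be finite numbers.")
  if (peak < 0) abort("`peak` must be >= 0 (ug P ml^-1).")
  if (spread_above <= 0 || spread_below <= 0)
    abort("`spread_above` and `spread_below` must be positive (mm).")
  if (pellet_depth <= 0)
    abort("`pellet_depth` must be positive (mm).")
  if (break_depth <= pellet_depth)
    abort("`break_depth` must lie below `pellet_depth`.")
  if (adsorbed_background < 0)
    abort("`adsorbed_background` must be >= 0.")
  structure(
    list(peak = peak, spread_above = spread_above, spread_below = spread_below,
         pellet_depth = pellet_depth, break_depth = break_depth,
         adsorbed_background = adsorbed_background),
    class = "initial_pulse"
  )
}

#' @export
print.initial_pulse <- function(x, ...) {
  cat("<initial_pulse>\n")
  cat(sprintf("  peak %.3g ug ml^-1 at z = %g mm; spread %g mm above / %g mm below;\n",
              x$peak, x$pellet_depth, x$spread_above, x$spread_below))
  cat(sprintf("  constant tail below z = %g mm; adsorbed background %.3g ug ml^-1\n",
              x$break_depth, x$adsorbed_background))
  invisible(x)
}

#' Evaluate the initial condition on a grid
#'
#' Samples the piecewise-Gaussian dissolved-P pulse and the uniform adsorbed
#' background at the grid nodes. The dissolved profile is
#' `peak * exp(-(z - z_p)^2 / (2 a^2))` above the pellet,
#' `peak * exp(-(z - z_p)^2 / (2 b^2))` between the pellet and the break
#' depth, and constant (continuous at the break) below it.
#'
#' @param pulse An [initial_pulse()].
#' @param grid A [column_grid()]; must extend below `break_depth`.
#' @return A tibble with columns `depth_mm`, `dissolved`, `adsorbed`
#'   (ug P ml^-1).
#' @examples
#' build_initial_condition(initial_pulse(), column_grid(70, 141))
#' @export
build_initial_condition <- function(pulse, grid) {
  stopifnot(inherits(pulse, "initial_pulse"), inherits(grid, "column_grid"))
  if (grid$length_mm <= pulse$break_depth)
    abort(sprintf(
      "Grid of length %g mm does not cover the pulse break depth %g mm.",
      grid$length_mm, pulse$break_depth))
  z <- grid$z_mm
  zp <- pulse$pellet_depth
  dz2 <- (z - zp)^2
  spread <- ifelse(z <= zp, pulse$spread_above, pulse$spread_below)
  dissolved <- pulse$peak * exp(-dz2 / (2 * spread^2))
  tail_value <- pulse$peak *
    exp(-(pulse$break_depth - zp)^2 / (2 * pulse$spread_below^2))
  dissolved[z > pulse$break_depth] <- tail_value
  tibble(depth_mm = z, dissolved = dissolved,
         adsorbed = rep(pulse$adsorbed_background, length(z)))
}
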