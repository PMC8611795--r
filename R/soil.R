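#' Soil physical specification
#'
#' Bundles the bulk properties of the packed soil column needed to convert
#' between pore-solution concentrations and whole-soil phosphorus contents.
#'
#' @param bulk_density Dry mass of soil per bulk volume, g ml^-1.
#' @param particle_density Dry mass per volume of solids, g ml^-1. The default
#'   2.65 is the standard quartz-dominated mineral soil value.
#' @param background_total_p Pre-fertilization total P content of the soil,
#'   ug P per g dry soil.
#'
#' @return An object of class `soil_spec`.
#' @examples
#' soil_spec(bulk_density = 1.26)
#' @export
soil_spec <- function(bulk_density, particle_density = 2.65,
                      background_total_p = 597) {
  stopifnot(is.numeric(bulk_density), length(bulk_density) == 1,
            is.numeric(particle_density), length(particle_density) == 1,
            is.numeric(background_total_p), length(background_total_p) == 1)
  if (!is.finite(bulk_density) || bulk_density < 0)
    abort("`bulk_density` must be a finite non-negative number (g ml^-1).")
  if (!is.finite(particle_density) || particle_density <= 0)
    abort("`particle_density` must be a finite positive number (g ml^-1).")
  if (bulk_density >= particle_density)
    abort("`bulk_density` must be smaller than `particle_density`: a packed soil always retains pore space.")
  if (background_total_p < 0)
    abort("`background_total_p` must be >= 0 (ug P g^-1 soil).")
  structure(
    list(bulk_density = bulk_density,
         particle_density = particle_density,
         background_total_p = background_total_p),
    class = "soil_spec"
  )
}

#' @export
print.soil_spec <- function(x, ...) {
  cat("<soil_spec>\n")
  cat(sprintf("  bulk density:      %.3f g ml^-1\n", x$bulk_density))
  cat(sprintf("  particle density:  %.3f g ml^-1\n", x$particle_density))
  cat(sprintf("  porosity:          %.3f\n", porosity(x)))
  cat(sprintf("  background total P: %.1f ug g^-1\n", x$background_total_p))
  invisible(x)
}

#' Soil porosity from bulk and particle density
#'
#' Computes the porosity phi = 1 - rho_b / rho_s, the volume fraction of the
#' bulk soil occupied by pores (here assumed water-saturated).
#'
#' @param soil A [soil_spec()].
#' @return Porosity as a fraction in (0, 1].
#' @examples
#' porosity(soil_spec(bulk_density = 1.26, particle_density = 2.65)) # 0.525
#' @export
porosity <- function(soil) {
  stopifnot(inherits(soil, "soil_spec"))
  1 - soil$bulk_density / soil$particle_density
}
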