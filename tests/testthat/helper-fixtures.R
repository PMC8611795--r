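# shared fixtures: coarse-soil reference truth and small fast grids

ref_truth <- function() {
  list(params = transport_params(1.6e-11, 2.7e-6, 5.2e-9),
       pulse = initial_pulse(900, 3, 12, 15, 27.5))
}

ref_truth_vector <- function() {
  c(diffusivity = 1.6e-11, adsorption_rate = 2.7e-6,
    desorption_rate = 5.2e-9, peak = 900, spread_above = 3,
    spread_below = 12)
}

# grid with nodes exactly on the pellet (15 mm) and break (27.5 mm) depths
aligned_grid <- function(n = 281) column_grid(70, n)

small_grid <- function() column_grid(70, 141)

short_schedule <- function() build_schedule(total_duration_h = 96)

# compact pulse (negligible tail) for attenuation/heat-kernel properties
compact_pulse <- function(spread = 3) initial_pulse(900, spread, spread, 15, 60)
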