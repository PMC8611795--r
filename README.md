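# pelletpulse

Phosphorus barely moves in soil: it diffuses slowly and binds avidly to
particle surfaces, so what happens in the first days after a fertilizer
pellet dissolves decides where the nutrient ends up. `pelletpulse` is an R
package for scientists who study that window with in-situ samplers
(microdialysis probes or suction cups) in packed soil columns. It provides:

* a forward model of the pulse — 1-D diffusion of dissolved P coupled to
  first-order adsorption/desorption on a saturated column with no-flux
  boundaries,
* virtual sampling of the column the way the devices report it (perfusion
  schedules, window-averaged readings, concentration-dependent recovery
  calibration, detection-limit censoring),
* a synthetic-experiment generator with the replicate noise structure of
  column studies, and
* the inverse problem: weighted least-squares estimation of the transport
  parameters and the initial pulse shape from probe time series.

## The model

Dissolved P ($c_{sol}$) and adsorbed P ($c_{ad}$), both in µg P ml⁻¹ of
pore solution, evolve on depth $0 < z < L$ as

$$\partial_t c_{sol} = D\,\partial_z^2 c_{sol} - \beta_1 c_{sol} + \beta_2 c_{ad},
\qquad
\partial_t c_{ad} = \beta_1 c_{sol} - \beta_2 c_{ad},$$

with $\partial_z c_{sol} = 0$ at both ends: no phosphorus enters or leaves,
and total P is conserved exactly. $D$ is the effective diffusivity
(m² s⁻¹), $\beta_1$/$\beta_2$ the adsorption/desorption rates (s⁻¹). The
rapid pellet dissolution is represented by its effective result, a
piecewise-Gaussian initial pulse (peak $c_{pulse}$ at the pellet, spreads
$a$ above and $b$ below, constant tail below a break depth). Parameters are
estimated by minimizing

$$R=\sum_{i,j}\frac{(c_{sol}(l_i,t_j)-\phi_{ij})^2}{\sigma_{ij}^2},$$

the residuals between model and the replicate means $\phi_{ij}$ at probe
depths $l_i$ and sampling windows $t_j$, weighted by replicate SDs
$\sigma_{ij}$.

## Worked example

Simulate the reference coarse-soil experiment (three microdialysis probes
around a pellet at 15 mm, six 2-h samples then daily 12-h samples for two
weeks, three replicate columns, 6% probe variability), then fit the model
back to the synthetic data:

```r
library(pelletpulse)

grid  <- column_grid()        # 70 mm column, 401 nodes
truth <- transport_params()   # D = 1.6e-11 m2/s, beta1 = 2.7e-6/s, beta2 = 5.2e-9/s
pulse <- initial_pulse()      # 900 ug/ml peak at 15 mm; spreads 3/12 mm

gen <- generate_dataset(truth, pulse, noise = noise_model(seed = 2), grid = grid)
gen$dataset
#> # A tibble: 57 × 8
#>   probe_id depth_mm window_start_h window_end_h mean_ug_ml sd_ug_ml     n
#> 1 P1             10              0            2       216.     22.4     3
#> 2 P1             10              2            4       215.     24.8     3
#> ...

fit <- fit_parameters(gen$dataset, fit_config(), grid)
fit
#> <pellet_fit>
#>   objective R = 1.157 over 45 observations; fit error 1.7%
#>   converged: TRUE (info 1, 509 function evaluations)
#>             term     estimate initial at_bound
#>      diffusivity 1.990227e-11 1.9e-11    FALSE
#>  adsorption_rate 2.706246e-06 3.1e-06    FALSE
#>  desorption_rate 8.167423e-09 3.6e-09    FALSE
#>             peak 8.583932e+02 8.5e+02    FALSE
#>     spread_above 2.993524e+00 3.0e+00    FALSE
#>     spread_below 1.333456e+01 1.2e+01    FALSE
```

Reading the output: the fit used the 45 observations recorded from 8 h
onward (windows starting earlier are excluded because the release itself is
faster than the model's initial condition). The adsorption rate and pulse
peak come back within a few per cent of the generating truth; the
diffusivity and desorption rate carry more uncertainty at a single noise
seed — they are identified by contrasts *between* probes, which the 6%
per-probe bias disturbs directly (see the methods vignette for the full
recovery study and a known upward bias of these two parameters under
correlated probe noise). `tidy(fit)`, `glance(fit)` and `autoplot(fit)`
give the broom-style parameter table, the one-row fit summary, and the
observed-versus-fitted figure per probe; `run_pipeline()` drives
simulate → generate → fit → report end-to-end from a single YAML
configuration (see `load_config()`), and `inst/cli/pellet-pulse` wraps the
same stages for shell use.

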