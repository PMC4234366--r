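# vdefsim

Simulation of bronchoconstriction, deep inspirations, and the emergence of
ventilation defects in a bifurcating airway tree.

## The problem

In asthma, constricted lungs ventilate patchily: imaging shows contiguous
clusters of poorly ventilated terminal units — ventilation defects
(VDefs) — even though the smooth-muscle stimulus is uniform. Deep
inspirations (DIs) dilate airway smooth muscle and can prevent this, but
their benefit depends on how large and how frequent they are, and fails
under some conditions. `vdefsim` is for researchers in respiratory
physiology and computational biomechanics who want to study these emergent
dynamics in a mechanistic, fully reproducible network model.

## The model in brief

A symmetric binary tree of `2^(G+1)-1` airways (Weibel-style adult
morphometry, `G = 12` at full scale) ends in `2^G` identical elastic
units. Within each 5 s breath the tree is an RC network solved at 10 ms
steps (constant-flow inspiration, passive expiration to PEEP); radii are
constant within a breath. Between breaths each airway relaxes toward the
steady-state radius `r*` predicted by its wall model from the peak
transmural pressure `P_tm` of the preceding breath:

    r(k+1) = r(k) + S_x (r*(k) − r(k)),   S_x = S_c = 0.05 (constricting)
                                          S_x = S_d = 0.33 (dilating)

The wall balance `P_pass(ρ) + P_a T_r w f(ρ)/ρ = P_tm` (ρ = r/r₀) is
bistable at high activation `T_r`: an open branch coexists with a
collapsed state, and parenchymal tethering couples each airway's `P_tm`
to how well its own subtree ventilates relative to the lung mean. That
interdependence feedback, seeded by a 1% random heterogeneity in wall
thickness, is what lets VDefs self-organize. Periodic DIs are
parameterized by their relative volume `V_DI/V_T` and cycle interval,
with tidal volumes rescaled so all conditions deliver the same mean
ventilation. Outcome measures include the fraction of closed units
(`F_c`, threshold 15% of mean ventilation; `F_c,mean` over the last DI
cycle), mean-normalized ventilation maps on a Mandelbrot-style grid, and
the 6 Hz input resistance with pre-/post-DI response statistics.

See `vignette("vdefsim-methods")` for the full model description,
parameter table, and calibration rationale.

## Worked example

A reduced-scale run (G = 8, 800 breaths = 4000 s) at maximal smooth-muscle
activation without DIs, versus the same lung protected by a DI of three
tidal volumes every 100 s:

```r
library(vdefsim)

cfg <- sim_config(generations = 8, T_r = 1, seed = 1,
                  schedule = di_schedule(interval = 400, ratio = 1))  # no DIs
traj <- run_simulation(cfg)
traj
#> <vdef_trajectory> G = 8 | breaths = 800 | T_r = 1
#>   DI: ratio 1 interval 400 s | final Fc = 0.156 | Fc,mean = 0.151

cfg_di <- sim_config(generations = 8, T_r = 1, seed = 1,
                     schedule = di_schedule(interval = 100, ratio = 3))
fc_mean(run_simulation(cfg_di))
#> [1] 0
```

Without DIs, 15% of the terminal units are closed over the last cycle
(`F_c,mean = 0.151`)
and the final ventilation is bimodal — a patchy defect pattern you can
draw with `plot(ventilation_map(traj$ventilation[800, ],
map_terminals_to_grid(traj$tree)))`. With a sufficiently large and
frequent DI the same lung, same seed, develops no defects at all
(`F_c,mean = 0`): the protective domain of DI conditions.

The resistance response to a single DI:

```r
rs <- resistance_series(run_simulation(
  sim_config(generations = 8, T_r = 1, seed = 1,
             schedule = di_schedule(100, 3))))
di_response(rs)$ratio      # R_post-DI / R_pre-DI
#> [1] 0.3083936
```

so the 6 Hz resistance right after the DI drops to ~31% of its pre-DI
value before the airways re-narrow.

Parameter sweeps over (interval, ratio, T_r, S_c, seed) grids run through
`run_sweep()` / `summarize_sweep()`, with figure matrices from
`render_figures()`; the same experiments are scriptable from a shell via
`inst/cli/vdefsim` (`simulate`, `sweep`, `figures`, `impedance-check`).

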