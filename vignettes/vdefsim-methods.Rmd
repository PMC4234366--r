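---
title: "Model and methods behind vdefsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods behind vdefsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vdefsim)
```

## The problem

During bronchoconstriction, ventilation does not degrade uniformly:
imaging shows patchy ventilation defects (VDefs) — contiguous clusters of
poorly ventilated lung units — emerging even though airway smooth muscle is
stimulated everywhere equally. Deep inspirations (DIs) dilate airways and
can prevent or reverse this, but their protective effect depends on how big
and how frequent they are, and fails in some conditions. `vdefsim`
simulates a full bifurcating airway tree in which VDefs arise
spontaneously from airway interactions, and measures how the relative DI
volume (`V_DI/V_T`) and the interval between DIs govern their emergence.

## Model structure

The lung is a symmetric binary tree of `2^(G+1) - 1` airways over
generations `0..G` (G = 12, i.e. 8191 airways and 4096 terminal units, at
full scale; G = 8 for the demo experiments, see *Problem sizes* below).
Airway lengths and fully dilated diameters follow a Weibel-style adult
morphometry table shipped as CSV (`default_morphometry()`); users can
substitute their own. Each terminal airway feeds one acinar unit, a linear
compliance `C = C_total / 2^G` with `C_total = 0.1 L/cmH2O`. Terminal-unit
positions map onto a square grid by alternating bisection (the
"Mandelbrot" layout), so neighbouring pixels of a ventilation map are
close in the branching hierarchy.

Three nested time scales:

1. **Within a breath (10 ms steps).** Airway radii are frozen; the tree is
   an RC network (Poiseuille resistances, terminal compliances) driven by
   a constant inspiratory flow for 2.5 s and passive expiration against
   PEEP (5 cmH2O) for 2.5 s. Each backward-Euler step is solved exactly by
   collapsing the tree bottom-up to a Thevenin equivalent and distributing
   pressures top-down (linear cost in the airway count). The solver
   records per-terminal delivered volume and each airway's peak transmural
   pressure.
2. **Breath to breath.** Each airway's predicted steady-state radius
   `r*` is computed from its peak transmural pressure of the breath just
   simulated, and the radius relaxes toward it:
   `r(k+1) = r(k) + S_x (r*(k) - r(k))`, with `S_x = S_c = 0.05` when
   constricting and `S_x = S_d = 0.33` when dilating (12 breaths/min).
3. **DI cycles.** One DI of volume `ratio x V_T` followed by `n - 1` tidal
   breaths, with `V_T = n V_mean / (n - 1 + ratio)` so every condition
   delivers the same mean ventilation.

## The single-airway wall model

The original single-airway constitutive relations this design follows are
published only in the primary references, so `vdefsim` ships its own
parameterization with the same functional role, calibrated to reproduce
the qualitative network behaviour (see *Calibration*). The wall balance at
relative radius `rho = r/r0` equates the applied peak transmural pressure
with

```
G(rho) = P_pass(rho) + P_a T_r w f(rho) / rho
P_pass(rho) = k_c (1 - 1/rho) + k_s (h(rho) - h(1)),  h(rho) = x^m/(1 - x^m), x = rho/rho_max
f(rho)     = exp(-(rho - 1)^2 / (2 sigma_f^2))
```

- `P_pass` is passive recoil: zero at full dilation, a soft `1 - 1/rho`
  compressive term, and a high-power logistic saturation that pins the
  radius near `rho_max = 1.02` under physiologic loads. The exponent
  `m = 7` confines the saturation to `rho > ~0.8`, so compressive
  behaviour is governed by `k_c` alone.
- The active term is Laplace pressure from circumferential muscle tension:
  proportional to activation `T_r`, wall-thickness factor `w`, a Gaussian
  force-length factor peaking at full dilation, and `1/rho`.

At high activation `G(rho)` is non-monotone: a collapsed state at the
minimum-radius cap (`rho = 0.01`, functionally closed but numerically
finite) coexists with an open equilibrium over a band of transmural
pressures. `steady_state_radius()` returns the stable root in whose basin
the airway's current radius lies, which realizes the history dependence
(hysteresis) of the radius dynamics; `bistability_scan()` exposes the
equilibrium structure directly.

## Transmural pressure and parenchymal tethering

For airway `j` at time `t` within a breath,

```
P_tm,j(t) = p_mid,j(t) + P_el0 + P_el(t) + tau * P_el,tidal(t) * (lambda_j(t) - 1)
```

where `p_mid` is the mid-airway luminal pressure (PEEP-referenced),
`P_el0 = 5 cmH2O` the recoil at PEEP, `P_el(t)` the mean elastic recoil
above PEEP, and the last term is parenchymal distortion: `lambda_j` is the
tidal expansion of `j`'s subtree relative to the tree mean, measured
within the breath (volume above the start-of-breath state). Writing
`P_el,tidal = dV_mean/C`, the distortion term reduces to
`tau (dV_sub - dV_mean)/C`, well-defined even at zero mean expansion. A
subtree that stops ventilating loses up to `tau * P_el,tidal` of outward
traction at peak inflation — the destabilizing interdependence feedback —
while an over-expanding region gains traction and dilates. `tau = 1.5` by
default.

Two deliberate choices here: the distortion references *tidal expansion*,
not absolute volume (absolute-referenced deviations are an order of
magnitude too small to differentiate airways against a 3 L resting
volume); and gas-trapped closed units, which stay near their trapping
volume all breath, have `lambda ~ 0` and therefore remain locked closed
during tidal breathing, while a large DI raises the luminal pressure at
their upstream junction and can push them back over the reopening
barrier.

## Why VDefs emerge

At `T_r = 1` and default ventilation, the homogeneous tree settles on the
open branch around `rho ~ 0.30`, with peak tidal `P_tm ~ 15 cmH2O` and the
fold (disappearance of the open branch) near 10 cmH2O. At that operating
point the terminal resistive time constants approach the inspiratory
time, so ventilation becomes sensitive to radius differences. The 1%
wall-thickness heterogeneity (`perturb_wall_thickness()`) seeds small
ventilation differences; under-ventilated subtrees lose tethering
traction, their `P_tm` falls toward the fold, their `r*` drops, and the
slow constriction (`S_c`) walks them across it into the collapsed state.
The redistributed flow raises `lambda` for the surviving units, which
dilate — a self-organized, bimodal pattern. At `T_r = 0.6` (baseline
tone) the balance is monotone at tidal pressures and nothing closes.

DIs protect by periodically raising peak `P_tm` well above the fold and
letting the fast dilation (`S_d = 0.33`) reset radii before the slow
re-narrowing (time scale `~1/S_c` breaths) can reach the fold again. This
is why the protective domain couples DI volume with DI interval, and why
doubling `S_c` behaves like doubling the interval — the basis of the
normalized-interval collapse (`normalized_interval()`).

## Calibration

The constitutive constants are a model choice, not measurements. They were
fixed, once, by requiring of the wall balance (at the default breath spec
and ventilation):

- counts of stable equilibria in {1, 2} at every activation, with the
  bistable pressure band contiguous;
- the band at `T_r = 1` (about 10-123 cmH2O) straddles the tidal peak
  `P_tm` (~15 cmH2O), with the fold close enough beneath it that the
  tethering feedback (reach ~ `tau * P_el,tidal ~ 7.5 cmH2O`) can cross
  it — the condition for emergence;
- the band at `T_r = 0.9` is strictly narrower than at 1.0, and the law
  is monotone at `T_r <= 0.6`;
- a passive airway (`T_r = 0`) stays within 1% of `r0` under tidal loads;
- the open-branch radius at tidal pressure (~0.30) puts terminal time
  constants near the inspiratory time, so ventilation is
  resistance-limited enough for the feedback to engage.

The shipped defaults are `k_c = 2`, `k_s = 4`, `m = 7`, `rho_max = 1.02`,
`P_a = 56 cmH2O`, `sigma_f = 0.42`. `export_rstar_curves()` writes the
resulting `r*(P_tm)` branches to CSV for inspection.

## Numerical choices

- Backward Euler is unconditionally stable and exactly volume-conserving
  here; halving the 10 ms step changes per-terminal ventilation by well
  under 0.5%.
- The steady-state solver brackets roots on a 240-point radius grid and
  refines by bisection to a balance residual below 1e-8 cmH2O; basin
  membership (narrowing vs dilating) picks the branch.
- The minimum-radius cap `rho = 0.01` keeps resistances finite (a capped
  airway's resistance is ~1e8 times its dilated value, functionally
  closed); the closed-airway sentinel for non-positive radii is
  1e9 cmH2O s/mL.
- Resistances are Poiseuille (`8 mu L / pi r^4`); the 6 Hz input
  resistance is the real part of the recursively collapsed impedance with
  terminal impedances `-i/(omega C)`, reported in cmH2O s/L.
- One RNG stream per run, seeded once: the wall-thickness draw is consumed
  first, the traced-airway subset second.
- For schedules without DIs, `F_c,mean` averages the final 400 s of
  breaths (degenerate-cycle convention).
- Radius traces store 256 randomly selected terminal airways; full
  per-breath radius matrices are kept only for trees with `G <= 9`.

## Problem sizes

The demo and test experiments run at G = 8 (511 airways, 256 terminal
units) with 800 breaths (4000 s), which preserves every qualitative
behaviour of the full G = 12 tree at roughly 1/16 the cost; full scale is
available through the same configuration surface (and the CLI's
`--full-scale`). Multi-seed ranges use 10 wall-thickness realizations.

One stabilization convention matters when comparing constriction speeds:
the time to reach the stable defect pattern scales with `1/S_c`, and at
`S_c = 0.05` some near-boundary DI conditions are still differentiating at
4000 s. Speed-index comparisons (the normalized-interval collapse) are
therefore made at equal *normalized duration* `S_c x t` — 800 breaths at
`S_c = 0.1` against 1600 breaths at `S_c = 0.05` — so both runs are at
their stable states.

## What the simulations do and do not show

The model reproduces, at reduced scale: bimodal ventilation and
`F_c,mean` far above zero at maximal activation without DIs; no defects at
baseline tone; a protective DI domain (e.g. ratio 3 every 100 s) next to
conditions whose DIs fail (ratio 1.2 every 400 s); weaker defects at
`T_r = 0.9` than 1.0; and the collapse of `F_c,mean` curves when plotted
against the `S_c`-normalized DI interval. These are emergent outcomes of
the calibrated network, not fitted targets.

Known limitations: no mucus plugs or liquid bridges (reopening pressures
are therefore optimistic); symmetric branching only; constant breath
timing; no gas inertance (the 6 Hz resistance uses R and C only); closed
airways reopen only through upstream luminal pressure, because the
within-breath expansion reference gives trapped units no tethering boost —
with the shipped constants the reopening barrier is high, so very large
DIs mostly *prevent* rather than *reverse* closure; and the constitutive
constants, while behaviourally calibrated, are not tissue measurements —
quantitative outputs (e.g. exact `F_c,mean` levels or resistance ratios)
should be read as characteristic of the model family, not of a patient.
```
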