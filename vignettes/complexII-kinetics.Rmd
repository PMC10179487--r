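---
title: "Kinetics of reverse electron transfer in complex II: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of reverse electron transfer in complex II: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system and the questions

Complex II (succinate dehydrogenase) couples the dicarboxylate chemistry
at its flavin site to the quinone chemistry at the membrane-facing Qp
site through a wire of one-electron carriers: the [3Fe-4S], [4Fe-4S] and
[2Fe-2S] iron–sulfur clusters, with heme *b* adjacent to the quinone
node.  In normoxia it oxidizes succinate and reduces ubiquinone; in
hypoxia/ischemia the quinone pool is driven reduced and the enzyme can
run backwards, reducing fumarate to succinate with ubiquinol (QH2) as the
electron donor.

`sdhkin` implements a mechanistic mass-action model of both directions to
answer three quantitative questions: (i) what Michaelis constants and
maximal rates the full catalytic cycle produces for QH2, Q, fumarate and
succinate; (ii) whether the reverse rate–QH2 relation shows the
"tunnel-diode" drop at high driving force known from electrode
experiments on the soluble SDHA/SDHB subcomplex; (iii) how much
superoxide and H2O2 the flavin, semiquinone and [3Fe-4S] sites produce at
steady state.

## Model structure

31 species, 35 elementary reactions (ids `1`–`29` with lettered variants
`8a`, `8b`, `16a`, `16b`, `17a`, `21a` for the fumarate- and
succinate-bound flavin).  All reversible steps follow
`V = k (Π substrates − Π products / Keq)` with concentrations in µM and
time in s.  Three reactions are irreversible as written: superoxide
dismutation (`27`, Michaelis–Menten in superoxide, Vmax 5.6e4 µM/s,
Km 50 µM), H2O2 efflux from the matrix (`28`, 30 /s), and the
inner-membrane quinone recycling (`29`, first order).

Fixed unit and clamping conventions:

* potentials in mV with the thermal voltage RT/F = 25 mV (the value the
  tabulated constants were derived with; configurable);
* H+ is a clamped species in µM, 0.1 µM at pH 7, entering each rate law
  exactly as the reaction is written;
* fumarate, succinate and O2 are clamped boundary conditions.  O2 has no
  literature-pinned value in this model's sources; the package default is
  **30 µM**, a mid-range tissue estimate, and every ROS magnitude scales
  with it — treat absolute ROS rates as conditional on that choice.

Seven moiety-conservation relations reduce the dynamics: the Qp-site
occupancy states, each redox-center pair, and the nine flavin states sum
to the enzyme content (235 µM, from 0.209 nmol/mg protein × 273 µM per
nmol/mg ÷ 0.24 membrane/mitochondrial volume ratio), and total quinone is
conserved when the pool is closed.  One species per active moiety is
eliminated algebraically (reconstructed from its pool total), so exactly
20 ODEs are integrated in every operating mode and conservation is exact
by construction, in the Newton phase as well as during integration.

### Thermodynamic consistency

Equilibrium constants of electron transfers come from midpoint
potentials, deprotonations from pKa values (10.86 for QH2/QH−, 5.31 for
QH•/Q•−).  Detailed balance is enforced two ways:

* the five flavin-site constants (`18`, `8a`, `8b`, `16a`, `16b`) are
  always recomputed from cycle-closure formulas
  (`Keq18 = exp(2(E(fum/suc) − E(FAD/FADH2))/25)/(Keq19·Keq17)` = 2778 at
  the defaults, etc.), so changing any dicarboxylate binding constant
  keeps all flavin cycles closed.  One published compilation quotes
  `Keq16b = 0.47` from an inconsistent intermediate value; the closure
  gives 0.30 and `thermo_check()` reports the difference rather than
  adopting it.  Steady-state fluxes are insensitive to this constant.
* `check_detailed_balance()` evaluates the six canonical cycles; the
  tabulated (rounded) constants close them to 0.2–4%, and
  `nernst_parameters()` regenerates an exactly balanced set from the
  potential table when exact equilibrium is needed (it also resolves the
  1 mV inconsistency between the tabulated one-electron flavin couples,
  −127/−30 mV, and the two-electron couple −79 mV).

The summed equilibrium constant of the detailed quinol-oxidation steps
(`Keq1·Keq2·Keq3·Keq9·Keq10·Keq11` = 8.2e-4 µM²) falls ~110-fold short of
the overall Nernst value for `QH2 + 2[3Fe-4S]` at E(Q/QH2) = 90 mV.
`apply_thermodynamic_adjustment()` closes the gap exactly as the model's
calibration prescribes: the semiquinone couple E(QH•/QH−) moves from the
solution value 190 mV to the membrane value 150 mV (Keq3 → 0.027,
Keq4 → 1.5e-6; a 4.9-fold gain), and the remaining 22.4-fold factor is
absorbed into the quinone binding/release product, fixing
`Keq1·Keq11 = 7.39` µM⁰ bookkeeping.  All figure presets carry this
linked constraint; `set_keq1()` moves along it.

### Operating modes and the quinone closure

Reaction 29 closes the quinone cycle.  Three modes are supported:

* **clamped-QH2** (reverse substrate scans): free QH2 is a parameter,
  free Q is dynamic and drained by `29` (Q → QH2);
* **clamped-Q** (forward scans): symmetric, `29` drains QH2 → Q;
* **conserved-pool** (dicarboxylate scans; default total 500 µM): `29`
  recycles the product quinone species back to the substrate species.

The tabulated `k29 = 1 /s` describes a slow background quinol supply; it
cannot carry the catalytic fluxes the scan configurations produce (the
recycling flux is bounded by `k29 × pool`).  In the scan presets the
closure therefore runs at the same **100 /s** base rate those
configurations assign to every quinone/dicarboxylate binding and release
step.  This single choice reproduces the published quinone-side
saturation parameters across modes (QH2, Q and succinate Km and Vmax to
within a few percent — see `scripts/acceptance.R` output), and the
package treats it as part of the scan conditions; `table2_base` keeps the
tabulated 1 /s.

### What the presets emulate

`table2_base` is the literature parameterization before adjustment;
`kd_ref10` / `kd_ref8` carry the bovine-enzyme (state-dependent, Kd
10–240 µM) and adjusted-model (state-independent, 355/1000 µM)
dicarboxylate constants; `fig1*`/`fig3*`/`fig4*` add the scan geometry
(direction, clamps, 500 µM pool for dicarboxylate scans, saturating
co-substrate 1000 µM, and `k1 = 200`, `k11 = 1e4 /s` for the fast-exchange
variant).  These are idealized single-enzyme conditions: no membrane
potential or pH dynamics, no distal Qd site or intra-pocket quinone
movement, heme *b* present but catalytically dispensable.  Passing tests
therefore demonstrate internal consistency with that idealization, not
fidelity to intact-mitochondria data.

## Steady states

`integrate_to_steady_state()` is a two-phase solver.  Phase 1 integrates
the reduced system with `deSolve::lsode` (BDF with full finite-difference
Jacobian; rtol 1e-9, atol 1e-9) over logarithmic checkpoints to
`t_max = 1e6 s`, stopping at the first checkpoint that is steady.  lsoda's
automatic stiffness switching fails on this system (rate constants span
1e-3–4.8e7, eigenvalue spread ~1e12), which is why the method is pinned.
Phase 2 polishes the root with a damped Newton iteration: forward/central
finite-difference Jacobian, column scaling by species magnitude, a
Levenberg fallback for near-singular steps, and step limiting to keep
concentrations non-negative.  Integrating first selects the physically
reached branch if the network were ever multistable; no multistability
has been observed across the preset grid (fully-oxidized and
fully-reduced starts agree to <0.1%).

**Round-off floor.** Several redox exchanges sit near equilibrium with
opposing one-way rates of order 1e8 µM/s, so a net rate is a cancellation
that double precision cannot resolve below ~1e-8 µM/s.  Convergence is
therefore declared when the scaled derivative norm
`max |dx/dt| / max(|x|, 1)` falls below `tol` (default 1e-10 /s) **or**
when every net rate is below 1e-11 of that species' gross one-way
turnover — the second criterion is the attainable floor and is what the
stiff presets converge on.  `residual_scaled` reports it.

Net turnover is read from the dicarboxylate side (succinate release
`V19 + V21 + V21a` in reverse; fumarate release in forward), which is
numerically clean, and audited against the quinone side through the exact
electron balance `dic = V29 ∓ bypass/2` with
`bypass = 2·V22 + V23 + V24 + V25 + V26`; a >1% discrepancy is an error.
At the package's 30 µM O2 the bypass is ~0.7% of turnover.

## Scans and Michaelis extraction

`substrate_scan()` solves one fresh steady state per grid point (25
log-spaced points by default; quinones over 0.01–1e4 µM, dicarboxylates
over 0.1–2e3 µM, the physiological range and the range the model's source
results cover).  Fresh solves make the scan order irrelevant by
construction, so any hysteresis verdict reflects the model, not solver
memory.

`michaelis_from_curve()` uses two regimes:

* when the curve has saturated (rate change <0.5% over the top decade),
  `Vmax` is the top-of-grid rate and `Km` the half-`Vmax` crossing,
  log-interpolated and refined by bisection on fresh solves to 0.5% —
  this is how a plateaued simulated curve is read, and it recovers exact
  hyperbolas to <1% on the default grid;
* when there is no plateau in range (the fumarate curves keep creeping a
  few %/decade past 1 mM because weak fumarate binding to FAD and FADH•
  saturates slowly), a top-of-grid `Vmax` would be grid-dependent and
  bias `Km`; the saturation parameters are instead estimated by
  nonlinear least squares on `v = Vmax·S/(Km+S)` over the scanned points,
  and `plateau = FALSE` marks the extrapolation.

`tunnel_diode_check()` calls a curve monotonic when no successive rate
difference drops below −0.1% of the maximum; otherwise it reports the
peak location and fractional drop.

## Known limitations

* **Low-substrate [3Fe-4S] poise.** With any irreversible
  quinol-regenerating closure, zero turnover leaves the quinone pool
  fully reduced, so the cluster's oxidized fraction tends to ~0 as
  fumarate → 0.  The source literature is split on this limit — one
  figure shows full oxidation at vanishing fumarate, while the same
  work's ROS argument requires the cluster largely reduced at small
  QH2/fumarate — and this model realizes the second behavior.  At
  saturating QH2 the oxidized fraction (0.24–0.30 across presets) stays
  far below the ~99% a tunnel-diode drop would need, consistent with the
  published bounds (<200 of 235 µM oxidized; recovery ≤80%).
* **Forward succinate Km under fast quinone exchange.** The fast-exchange
  forward curve is steeply sigmoidal with half-saturation near 50 µM,
  above the published 37 µM, and insensitive to the closure rate; the
  same preset's quinol and fumarate constants are reproduced.  The
  corresponding acceptance check is kept at the published value and
  fails, documenting the discrepancy.
* **Absolute ROS rates** are conditional on the O2 clamp and on the
  [3Fe-4S] poise; with 30 µM O2 the [3Fe-4S]− site dominates superoxide
  production.  The package reports per-site attributions
  (`ros_report()`); treat totals as order-of-magnitude under the stated
  O2.
* **Extreme binding constants** (Keq1 ≳ 1e3 µM⁻¹, i.e. sub-nM quinone
  dissociation) are outside the regime the closure was validated in;
  maximal-rate values there are less certain, although monotonicity
  verdicts are robust.

## Problem sizes

Default scans use 25-point grids (one stiff steady-state solve each, tens
of milliseconds); the full acceptance recomputation
(`scripts/acceptance.R`: six scans, six single-point solves, one analytic
constant) runs in about two minutes on one core.  Everything is
deterministic; there is no random number use outside test fixtures.
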