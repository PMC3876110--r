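---
title: "A human ventricular myocyte model with restricted extracellular spaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A human ventricular myocyte model with restricted extracellular spaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In ventricular cardiomyocytes a large share of the sarcolemma lies inside
t-tubules, narrow invaginations whose lumen communicates with the
interstitium only through the tubule mouth, and the interstitium itself is
a thin cleft between neighbouring cells rather than a well-stirred bath.
Every beat moves substantial amounts of Ca2+, K+ and Na+ across these
membranes, so the ion concentrations the channels and transporters actually
see can deviate from the bulk values: Ca2+ is transiently depleted where
the L-type current is dense, K+ accumulates during repolarization. `ttmyo`
implements a deterministic ODE model of a single human ventricular myocyte
in which the extracellular medium is resolved into

* a t-tubular lumen discretized into **nine concentric cylindrical shells**
  (shell 1 adjacent to the tubular membrane, shell 9 the axial core),
* a single well-stirred **intercellular cleft** layer facing the surface
  membrane, and
* an infinite, fixed **bulk** reservoir,

so that accumulation-depletion in the restricted spaces feeds back on
membrane transport, the action potential and the cytosolic Ca2+ transient.

## Model structure

One shared membrane potential `V` drives two membrane pools: the surface
pool, exposed to the cleft concentrations, and the tubular pool, exposed to
the concentrations of shell 1. Each of the thirteen current families
(`I_Na`, `I_Naps`, `I_CaL`, `I_Kto`, `I_Kr`, `I_Ks`, `I_K1`, backgrounds,
`I_K(Na)`, `I_ns(Ca)`, `I_NaCa`, `I_NaK`, `I_pCa`) is split between the
pools by its t-tubular fraction `f_x,t`; with the basic settings most
fractions equal the t-tubular membrane-area fraction 0.56, while
`f_CaL,t = 0.64`, `f_K1,t = 0.67` and `f_pCa,t = 0.2` follow the
animal-derived asymmetries used for the basic model. Gating states are
shared between the pools: all transition rates depend either on the
common membrane potential or on shared intracellular compartments (the
Ca2+-dependent inactivation of `I_CaL` senses the single dyadic space), so
duplicating them per pool would change nothing while doubling the state.

Fast Na+ activation is a four-state Markov chain (three identical
subunits) with Hodgkin-Huxley fast/slow inactivation gates; the L-type
channel combines a three-state activation chain with voltage-dependent
(`f`, `f2`) and dyadic-Ca2+-dependent gates and a GHK driving force; the
delayed rectifiers and the transient outward current use standard
epicardial-kinetics gate formulations; the RyR is the four-state
Ca2+-activated scheme with an adapted state. Intracellular Ca2+ cycles
through cytosol, dyadic space, network and junctional SR with a
forward-reverse SERCA pump and four dynamically integrated buffers
(calmodulin, high- and low-affinity troponin sites, calsequestrin).
Buffers are full ODE states rather than rapid-buffering approximations
because buffer occupancies are first-class model compartments here.

### Extracellular exchange

Three transport processes connect the extracellular compartments:

1. **Radial diffusion** between adjacent shells, with interface
   conductance `D_eff * A / dr` from the cylindrical geometry. The
   effective radial diffusivities are deliberately far below free-solution
   values (5e-9 cm²/s for Ca2+): with free diffusion a sub-micron lumen
   mixes in microseconds and the shell discretization would be inert. The
   reduced values are calibration constants chosen so that radial
   gradients of the published size and ordering (shell 1 most depleted
   during the L-type current) appear; they lump tortuosity, luminal
   macromolecular crowding and the unresolved axial direction.
2. **Mouth exchange** between the volume-weighted mean tubular
   concentration and the cleft with time constant `tau_x,ct`
   (`tau_Ca,ct = 240 ms`; K+ and Na+ scaled by their free-solution
   diffusion-coefficient ratios: 97 and 143 ms). The flux is distributed
   over the shells as a uniform rate so that total lumen mass changes only
   through the mouth and the membrane.
3. **Cleft-bulk exchange** with per-ion time constants (Ca2+ 24.7 s,
   K+ 10 s, Na+ 14.3 s). The K+ value pins the experimental ~10 s onset of
   interstitial K+ accumulation; the set matches the atrial-cleft
   formulation the cleft layer is modelled after.

The bulk is an infinite, fixed reservoir, equivalent to perfect perfusion.

## Stimulus, clamp modes, state

The stimulus is a rectangular 3-ms current pulse at 1.2x the diastolic
threshold (the default amplitude, -1800 pA, was determined programmatically
with `find_stim_threshold()`). Stimulus charge is booked as K+ entering the
cytosol, the convention that keeps multi-hour runs mass-conserving; a
consequence worth knowing is that at steady pacing the stimulus charge must
leave the cell again through K+ channels, which sustains a small
(~0.1-0.2 mM) elevation of cleft K+ above bulk proportional to pacing rate.

Clamp modes reproduce the reference experiments: `clamp_cleft` and
`clamp_all_extracellular` pin the cleft (or cleft plus all nine shells) at
bulk values with identically zero derivatives, isolating the effect of
concentration dynamics; `fix_intracellular_NaK` dialyses intracellular Na+
and K+ at pipette values (10 and 130 mM) for the 15-pulse AP validation
protocol.

The full state has 73 components: voltage, 21 gating/Markov states, 10
intracellular concentration and buffer states, 27 tubular and 3 cleft
concentrations, and 11 quadrature accumulators that integrate the
Ca2+-carrying currents and the cytosolic Ca2+ concentration inside the
solver, so per-cycle integrals inherit solver accuracy instead of
trace-sampling accuracy. The layout is versioned and queryable via
`state_layout()`.

## Numerics

The stiff system is integrated with `deSolve`'s `lsoda` (`rtol = 1e-6`,
per-block absolute tolerances down to 1e-11 for cytosolic and dyadic Ca2+),
restarted at each stimulus edge so discontinuities never cross a solver
step; `vode` serves as an automatic fallback for the rare near-equilibrium
states where `lsoda`'s stiffness switching stalls. Each cycle's
accumulators are reset at the stimulus, and the end-diastolic sample is the
state immediately before the next stimulus. Halving the tolerances moves
APD90 by well under 0.5 ms at 1 Hz (asserted in the test suite).
`initial_state()` finds the quiescent equilibrium by integrating the
unstimulated model until the scaled derivative norm falls below tolerance,
warm-started from a stored seed for the basic parameter set.

## Calibration

Only part of the parameter set is printed in the sources this model
follows; the remainder was calibrated, once, against the published
benchmark numbers, and every calibrated entry is flagged in
`default_parameters()` (and in the shipped `basic_model.yaml`). The main
calibrated groups:

* background conductances, pump scale and SERCA rates, set so the
  quiescent cell rests at 63.6 nM cytosolic Ca2+ and 9.3 mM Na+ with a
  stable SR load;
* the lumped tubule radius/volume and the radial diffusivities, set so
  the steady-state free-vs-clamped comparisons give per-cycle Ca2+-entry
  reductions of ~5 amol (1 Hz) and ~7 amol (2.5 Hz) and Ca2+-transient
  integral reductions of ~2% and ~3%;
* the cleft volume (3.5 pL), which positions the 3-Hz-train cleft K+
  accumulation near +0.8 mM with its ~10 s onset and ~200-280 s in-train
  decay;
* the Na+/K+ pump, whose voltage dependence is largely flattened
  (`nak_v_flat = 0.8`) and whose Na+ activation is a steep Hill function
  (Km 10 mM, exponent 2): the pump then responds to rate changes mainly
  through slow intracellular Na+ accumulation, which is what gives the
  cleft K+ transient its observed rise-then-decay shape instead of being
  quenched within a few beats.

## Known limitations

* The frequency-step transients are weaker than the published ones: 10 s
  after a 1-to-2.5 Hz step this model suppresses the Ca2+-transient
  integral by ~4-5% (published ~15%) and APD90 by ~3-4 ms (published
  ~13 ms), and the fast cleft Ca2+ fall at a 3-Hz train is ~0.07-0.10 mM
  (published ~0.25 mM). The root cause is structural: this plateau is
  carried less exclusively by `I_CaL` (so APD is less sensitive to
  extracellular Ca2+ depletion), and SR loading grows less steeply with
  rate, so the net Ca2+ uptake transient that empties the cleft after a
  rate step is smaller. Deepening these effects by shrinking the cleft or
  slowing cleft-bulk exchange was explored and rejected: it breaks the
  recovery time constants (~46-50 s) and the steady-state comparisons that
  the model does reproduce.
* No axial (longitudinal) discretization of the tubule, no tubule
  branching or lumen deformation, uniform transporter density along the
  tubular membrane.
* Deterministic RyR gating and a single lumped dyadic space shared by
  both membrane pools; no spatial dyadic gradients.
* Single cell, current-clamp only; one epicardial-like AP phenotype at a
  single temperature (310 K).
* A paced cell is only quasi-periodic: intracellular Na+ approaches its
  frequency-dependent level over hundreds of seconds, which is why the
  reference protocols pace for 1200 s before steady-state readouts.

## Problem sizes used in the shipped checks

Unit and property tests run on short runs (typically 10 paced cycles, with
dense 1-ms traces of the last cycles). The acceptance-level reproductions
use the reference protocol sizes: 1200 s of pacing per steady state (free
and clamped, 1 and 2.5 Hz), 300 s of observation after the frequency step,
and a 700 s train at 3 Hz; on one CPU the whole set integrates roughly
9,000 s of model time in a few minutes.

## A worked example

```{r, eval = FALSE}
library(ttmyo)

params <- default_parameters()
rest <- initial_state(params)
1e6 * rest[["ca_i"]]   # resting cytosolic Ca2+, nM
rest[["na_i"]]         # resting Na+, mM

sim <- simulate_model(rest, params, pacing_protocol(c(1, 10)),
                      record = 10, sample_ms = 1)
glance(sim)
autoplot(sim, vars = c("v", "ca_i", "ca_t1", "k_c"))
```
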