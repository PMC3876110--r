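# ttmyo

Deterministic ODE model of a **human ventricular cardiomyocyte with
restricted extracellular spaces**, for cardiac electrophysiologists and
modellers who want to ask how activity-dependent ion
accumulation-depletion outside the cell feeds back on membrane transport
and Ca²⁺ cycling inside it.

Most ventricular cell models treat the extracellular medium as an infinite
bath. In a real myocyte, much of the sarcolemma lines narrow t-tubules and
the rest faces a thin intercellular cleft; each beat depletes Ca²⁺ and
accumulates K⁺ in these restricted volumes. `ttmyo` resolves the
extracellular side into a **nine-shell t-tubular lumen** (concentric
cylindrical shells, shell 1 at the membrane), a single **cleft** layer and
an infinite **bulk** reservoir, coupled by radial diffusion, tubule-mouth
exchange (τ_Ca,ct = 240 ms) and per-ion cleft–bulk exchange. A single
membrane potential drives surface and tubular membrane pools; each of the
thirteen current families I_Na, I_Naps, I_CaL, I_Kto, I_Kr, I_Ks, I_K1,
I_b, I_K(Na), I_ns(Ca), I_NaCa, I_NaK, I_pCa splits between the pools by
its t-tubular fraction f_x,t (basic model: f_CaL,t = 0.64,
f_NaCa,t = 0.56, f_pCa,t = 0.2, others mostly 0.56). Intracellular Ca²⁺
cycles through cytosol, dyadic space, NSR and JSR with SERCA uptake J_up,
four-state RyR release and dynamic buffers (calmodulin, troponin,
calsequestrin). Per membrane pool the model tracks the net cycle Ca²⁺
transfer

    n_Ca,net = (1/2F) ∫_T ( I_CaL − 2·I_NaCa + I_Cab + I_pCa ) dt

whose surface and tubular parts cancel at steady state
(n_Ca,net,s + n_Ca,net,t ≈ 0).

The right-hand side is compiled C integrated by `deSolve`'s stiff solvers;
per-cycle integrals are carried as quadrature states inside the solver.
Results come back as tidy tibbles (`tidy()`, `glance()`, `autoplot()`).

## Worked example

```r
library(ttmyo)

params <- default_parameters()      # the calibrated basic model
rest <- initial_state(params)       # quiescent equilibrium
1e6 * rest[["ca_i"]]
#> [1] 63.5                         # resting cytosolic Ca2+ (nM)
rest[["na_i"]]
#> [1] 9.33                         # resting intracellular Na+ (mM)

sim <- simulate_model(rest, params, pacing_protocol(c(1, 10)),
                      record = 10, sample_ms = 1)
glance(sim)
#>   n_cycles t_total_s v_end ca_i_end na_i_end k_c_end ca_c_end n_ca_net_total
#> 1       10        10 -83.3 5.82e-05     9.48    5.69     2.15           1.03

apd(dplyr::filter(sim$trace, cycle == 10), 0.9)
#> [1] 256.2                         # APD90 (ms) of the 10th AP
```

The ten-cycle summary shows the model still approaching its paced steady
state: end-diastolic Vm −83.3 mV, diastolic Ca²⁺ 58 nM, cleft K⁺
transiently at 5.69 mM, and a net cycle Ca²⁺ transfer of ~1 amol that
shrinks toward zero as pacing continues. Protocol helpers
(`pace_to_steady_state()`, `frequency_step()`, `train_protocol()`,
`ap_validation()`, `freq_dependence()`, `sweep_fractions()`) reproduce the
reference experiments; `clamp_config()` pins cleft and/or tubular
concentrations at bulk to isolate the effect of extracellular dynamics. A
command-line front end is installed at `exec/ttmyo` with the matching
subcommands.

See the vignette (`vignettes/restricted-extracellular-spaces.Rmd`) for the
model description, calibration rationale and known limitations.

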