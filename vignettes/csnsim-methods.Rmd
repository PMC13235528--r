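---
title: "Model and methods: delay-tuned combination sensitivity in csnsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: delay-tuned combination sensitivity in csnsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`csnsim` simulates how a combination-sensitive neuron (CSN) can respond
selectively to an ordered pair of stimuli separated by hundreds of
milliseconds. This vignette is the package's own account of the model:
the equations, the parameters that matter, the design choices made where
the design was genuinely open, what the experiment drivers do and do not
establish, and known limitations.

## 1. Single-neuron model

Every neuron is a single electrical compartment,

$$C_m \frac{dV}{dt} = -I_L - I_K - I_{Na} - I_A - I_{CaL} - I_{CaT}
  - I_{SK} - I_H - I_{syn} + I_{app},$$

with the currents in their standard forms: ohmic leak
$I_L = g_L (V - V_L)$; delayed rectifier $I_K = g_K n^4 (V - V_K)$; fast
sodium $I_{Na} = g_{Na} m_\infty^3(V)\, h\, (V - V_{Na})$ with
instantaneous activation and rate-constant inactivation kinetics
($\alpha_h = 0.128\,e^{-(V+15)/18}$,
$\beta_h = 4/(1 + e^{-(V+27)/5})$); an A-type potassium current
$I_A = g_A a_\infty(V)\, e\, (V - V_K)$ whose inactivation gate $e$ is
dynamic; and calcium currents in Goldman–Hodgkin–Katz form with driving
term $\mathrm{ghk}(V) = \mathrm{Ca}_{ex}\, V / (1 - e^{2FV/RT})$, the
removable singularity at $V = 0$ handled by a series expansion
(`ghk_drive()`).

Two currents carry the post-inhibitory rebound machinery:

* **T-type calcium**,
  $I_{CaT} = g_{CaT}\, a_{T\infty}^3(V)\, b_{T\infty}^3(r_T)\,
  \mathrm{ghk}(V)$. Activation $a_T$ is instantaneous; inactivation is an
  instantaneous function $b_{T\infty}(r_T)$ of a slow availability
  variable $r_T$ with $b_{T\infty}(0) = 0$ exactly (offset-subtracted
  sigmoid). Hyperpolarization raises $r_{T\infty}$, so availability
  accumulates during inhibition with the voltage-dependent time constant
  $\tau_{rT}(V) = \tau_{r0} + \tau_{r1}/(1 + e^{(V-\theta_{rr})/\sigma_{rr}})$.
  This variable *is* the primed state: everything the network does
  upstream of the CSN ultimately moves $r_T$.
* **H current**, $I_H = g_H [k_r r_f + (1 - k_r) r_s](V - V_h)$ with a
  fast and a slow hyperpolarization-activated gate ($V_h = -30$ mV). Its
  activation midpoint sits at $-95$ mV (within the $-85$ to $-95$ mV
  range appropriate for strong rebound without requiring deep
  hyperpolarization), so the current is minimal at rest and recruited
  during the inhibition-dominated integration window.

Class `HVC_X` (excitatory projection neurons, 8 ODEs) adds an
intracellular calcium pool,
$d[\mathrm{Ca}]_i/dt = -f \varepsilon (I_{CaL} + I_{CaT}) -
k_{Ca}([\mathrm{Ca}]_i - b_{Ca})$, driving the SK adaptation current
$I_{SK} = g_{SK}\, [\mathrm{Ca}]_i^2 / ([\mathrm{Ca}]_i^2 + k_s^2)\,
(V - V_K)$. The pump term is implemented with the sign that relaxes
calcium to its basal level (the divergent sign would be inconsistent
with transient calcium elevations). Class `HVC_INT` (interneurons,
7 ODEs) has no calcium pool and $g_{SK} = 0$ pinned; a large delayed
rectifier with a low-threshold activation midpoint makes its spikes
undershoot the resting potential.

Units are mV, ms, nS, pA, pF throughout (nS·mV = pA, pA/pF = mV/ms).
The GHK scale $\mathrm{Ca}_{ex}$ is an *effective* constant per neuron:
it absorbs the unit conversion between the dimensionless gating terms
and picoampere currents, so the nanosiemens values quoted for
$g_{CaT}$/$g_{CaL}$ produce working low-threshold bursts. Reconstructed
currents are reported in these model-defined arbitrary units.

## 2. Synapses

AMPA and GABA$_A$ synapses are first-order kinetic conductances: the
open fraction obeys $ds/dt = a_r [T](V_{pre})(1 - s) - a_d s$ with the
sigmoidal release function
$[T] = T_{max} / (1 + e^{-(V_{pre} - V_T)/K_p})$
($T_{max} = 1$, $K_p = 5$ mV, $V_T = 2$ mV), and the postsynaptic
current is $g\, s\, (V - V_{rev})$. Rates are per millisecond:
GABA$_A$ $a_r = 5$, $a_d = 0.18$; AMPA $a_r = 1.1$, $a_d = 0.19$.
Reversal potentials are not constrained by the circuit description
itself; AMPA reverses at 0 mV. For GABA$_A$ we use $-95$ mV rather than
the textbook $-80$ mV: the CSN reaches $\approx -89$ mV during the
integration window, and inhibitory conductance is its only
hyperpolarizing drive, so the reversal must lie below that value. This
is the one place where we overrode an a-priori default because the
implementation proved it infeasible. Transmission is instantaneous
through $[T](V_{pre})$; axonal delays are not modeled.

## 3. Network architecture

`build_full_network()` wires 12 neurons and 18 directed synapses.
Stimulus S1 drives the A-selective neuron; A excites E1, which drives
both the delay loop (E1→I1, I1⊣E2, E2→I2, I2⊣E3, with E3→I1 feedback
closing the loop) and the first feedforward interneuron I\_A1. The
interneurons I\_A1–I\_A3, driven sequentially by E1–E3, converge on the
CSN with GABA$_A$ synapses. S2 drives neuron B, which excites the CSN
directly (AMPA, 2.4–4 nS band) and excites I\_B, which in turn silences
I1, I2, I\_A2 and I\_A3 — targeted disinhibition that releases the CSN
exactly when the excitatory readout arrives. I\_B does not inhibit
I\_A1, and S2 reaches I\_B through a B→I\_B synapse (a single S2 entry
point; driving I\_B directly instead is an equivalent reading of the
circuit and can be emulated by adding a pulse on I\_B).

The chain edges I1⊣E2 and I2⊣E3 are inhibitory *by design*: E2 and E3
fire by post-inhibitory rebound at the offset of their inhibition, which
is what converts one stimulus duration into a self-propagating sequence
of rebound bursts — the temporal buffer. E2/E3 use fast availability
kinetics ($\tau_{r0} = 20$ ms when hyperpolarized) and strong
$g_{CaT}/g_H$ so a 30–50 ms inhibitory epoch suffices for a prompt
rebound burst; slow calcium clearance ($k_{Ca} = 0.013$/ms) accumulates
SK adaptation *across* rebound cycles, so the loop runs down and dies
after roughly three cycles (~260 ms after S1 offset) instead of
reverberating forever. The CSN instead uses slow availability build-up
($\tau \approx 50$–80 ms at hyperpolarized voltages) — that slowness is
what makes its priming grow with delay — and a steep, relatively
depolarized T activation gate ($\theta_{aT} = -60$, $\sigma_{aT} =
-4.5$): the T current only ignites when membrane potential exceeds
about $-60$ mV, which after deep inhibition requires the joint push of
the H-current rebound and the AMPA drive from B. That conjunction is
the coincidence detector.

## 4. Stimuli and protocols

Stimuli are DC pulses (default 50 ms, 200 pA) applied to the selective
input neurons; the default intensity makes an isolated input neuron fire
at 200 Hz. S1 always starts at $t = 100$ ms — the first 100 ms double as
a settling period — and S2 starts `delay` ms after S1 offset; negative
delays express premature (overlapping) arrival. Pulse windows are
half-open $[t_0, t_0 + d)$. Control protocols cover reversed order,
single stimuli and same-stimulus repeats. The simulation horizon
defaults to the last pulse offset plus 400 ms so post-burst dynamics and
late recoveries are captured.

## 5. Numerics

The assembled system (8 or 7 ODEs per neuron plus one per synapse; 108
for the full network) is integrated by `deSolve` through a compiled C
right-hand side; a pure-R reference implementation of the same equations
(`assemble_system()`) is cross-checked against it in the test suite.
`lsoda` is the default method; Bogacki–Shampine 2(3) and Dormand–Prince
4(5) are available as the two explicit adaptive methods, and a BDF
fallback exists for stiff exploration. Tolerances default to
`rtol = 1e-6`, `atol = 1e-8` — tighter than typical defaults because
rebound timing is threshold-sensitive — and the integration is split at
every pulse edge so the solvers never step across a discontinuity in the
applied current. Output is resampled on a uniform grid: 0.01 ms for
single trajectories, 0.05 ms inside the sweep drivers (spike detection
at −20 mV with 1 ms dead time is insensitive to this choice, and the
coarser grid keeps the 100+-run drivers fast). Rest states are found by
2 s of relaxation followed by a damped Newton refinement to
$|dy/dt| < 10^{-6}$ in every component.

Spike detection uses upward crossings of −20 mV with a 1 ms dead time;
the acceptance anchors are insensitive to ±10 mV shifts of this
threshold. A combination is scored successful when the CSN fires 4–12
spikes spanning at most 80 ms, counted over the whole run (the CSN is
silent outside the facilitated burst by construction). H-current
recruitment is quantified as the peak |I_H| over the inter-stimulus gap
window (S1 offset to S2 onset — the reference [150, 150 + delay] window
generalized to non-default S1 durations), and T-current recruitment as
the peak |I_CaT| over the 100 ms window after S2 onset, each normalized
to its maximum across the delay set.

## 6. Experiment drivers and default grids

`run_delay_sweep()` (0–300 ms in 20 ms steps, 16 runs),
`run_heatmap()` (two parameter paths, e.g. `CSN.gCaT` ×
`CSN.gH` or `syn.I_A2->CSN` × `syn.B->CSN` at a 50 ms delay),
`run_stimulus_sweeps()` (10 × 10 duration or intensity grids, 10–200 ms
and 10–300 pA) and `run_oat_search()` (multiplicative ×1.25 outward
steps refined by bisection to ~2 significant figures, predicate =
paired success ∧ control failure) reproduce the analysis battery. Ranges
written as start–stop-by-step pairs are easy to get wrong (a 0.4–0.9 nS
range in 0.05 nS increments is 11 values, which no round m × n grid
matches), so the drivers take explicit value lists and the defaults use
round counts over the same ranges. Every grid cell
is one deterministic simulation; results are independent of execution
order, and each driver can emit a results table plus a JSON manifest
(axes, solver settings, configuration hash) from which the output can be
regenerated.

## 7. Calibration

Not every kinetic constant of these cell types is pinned down by
published measurements. The shipped defaults
(`default_network_config()`, mirrored in
`inst/extdata/default_network.yaml`) were therefore calibrated against
the model's reference behaviors, holding fixed its stated operating
point (stimulus 50 ms/200 pA at 200 Hz; CSN $g_{CaT} = 0.4$ nS within
[0.4, 0.9]; CSN $g_H = 6$ nS within [2, 30]; $g_{SK}$ within [0.1, 10];
synaptic conductances within 5–30 nS, B→CSN within 2.4–4 nS; synapse
kinetics as in §2). Calibration proceeded bottom-up: single-cell firing
(200 Hz anchor, sag, rebound, adaptation, interneuron undershoot), then
motif behavior, then loop timing and longevity, then the CSN's
delay-tuning curve. Because every anchor is an integer spike count, the
objective is piecewise constant and was explored by directed
one-dimensional scans rather than gradient methods; the final
neighborhood was checked by grid search.

With the shipped defaults the model reproduces: the 200 Hz single-cell
anchor; 4 CSN spikes at a 50 ms delay; an integration-window minimum of
−89.8 mV (vs. ∼−89); the 7-spike maximum over 100–140 ms first-stimulus
durations; a rise–peak–collapse delay-tuning profile with failure from
240 ms onward; complete order- and stimulus-selectivity of the full
network; and the motif-level dissociation (facilitation motif succeeds
only at near-zero gap; summation motif is order-insensitive and
stimulus-unspecific). It places some graded anchors one to a few spikes
off their reference values (6 spikes at 150 ms is measured as 5; the
$g_{CaT}$ staircase runs about one spike steep at its top; the reference
non-monotonicity at 230 ms delay — 9 spikes at 0.7 nS but 3 at 0.9 nS —
does not emerge). See §9.

## 8. What the generator emulates — and what it does not

The stimulus module emulates the study conditions exactly as specified:
square DC pulses standing in for stimulus-selective afferent drive, all
timing conditions (paired at any delay, overlap, reversed, singles,
repeats), and parameter grids over duration and intensity. It does not
emulate acoustic structure, spectro-temporal tuning, trial-to-trial
variability or background synaptic noise: the model is deterministic, so
passing tests demonstrate the circuit mechanism under idealized drive,
not robustness to biological noise or natural stimuli.

## 9. Known limitations

* **Discrete loop rundown.** The delay loop's decay is carried by SK
  accumulation in E2/E3 and is effectively all-or-none per cycle: the
  inhibition on the CSN stays deep until the loop dies (~360 ms after
  S1 onset) and then vanishes. In the target behavior the late
  integration window wanes *gradually*, which is what makes long-delay
  responses shrink smoothly, lets high-$g_{CaT}$ cells fire premature
  rebounds near the end of the window, and lets the H-current
  quantification decline at very long delays. This single structural
  difference accounts for the residual anchor mismatches noted in §7
  and for the windowed |I_H| peak not declining at a 280 ms delay.
* **Burst size is partly readout-limited.** The CSN burst terminates
  when availability runs down or the B input ends, so spike counts step
  with the AMPA-overlap duration; the graded ±1 spike structure of the
  delay curve between 60 and 200 ms reflects loop-phase alignment as
  well as priming depth.
* **Input-neuron latency.** Stimulus-selective neurons fire their first
  spike ~4 ms after pulse onset, so all event times carry a small
  systematic lag relative to an idealized instantaneous-onset reading.
* **Single cells per node.** Each node is one neuron, not a population;
  population-size scaling, heterogeneity, short-term plasticity,
  neuromodulation and multicompartment structure are out of scope.
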