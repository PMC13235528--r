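# csnsim

Conductance-based network model of stimulus-specific combination
sensitivity.

Combination-sensitive neurons (CSNs) fire only when two stimuli arrive in
the right order and with the right timing. In songbird auditory circuits
(nucleus HVC), this selectivity spans inter-stimulus gaps of hundreds of
milliseconds — far longer than any single synaptic or membrane time
constant. `csnsim` implements a biophysical circuit model of how such
long-delay selectivity can arise: an upstream *transient reverberatory
delay loop* (TRDL) keeps a trace of the first stimulus alive as a chain of
post-inhibitory rebound bursts, a *feedforward inhibitory convergence*
(FFIC) pathway converts that activity into sequenced inhibition of the
CSN, and the inhibition *primes* the CSN — de-inactivating its
low-threshold T-type calcium current and activating its H-current — so
that a precisely timed second stimulus triggers a rebound burst through a
narrow coincidence window.

The package is aimed at computational and systems neuroscientists who
want to simulate, perturb and quantify this class of delay-tuned circuit:
every neuron, synapse and stimulus is an explicit model object, and the
analysis stage (spike detection, burst classification, windowed current
quantification, parameter sweeps, sensitivity analysis) is part of the
package.

## The model

Each neuron is a single-compartment Hodgkin–Huxley-type cell,

```
Cm dV/dt = −IL − IK − INa − IA − ICaL − ICaT − ISK − IH − Isyn + Iapp
```

with instantaneous activation gates `x∞(V) = 1/(1 + exp((V − θx)/σx))`
and first-order kinetics for the dynamic gates (n, h, e, rT, rf, rs).
Excitatory projection neurons (class `HVC_X`, 8 ODEs) carry an
intracellular calcium pool driving an SK-type adaptation current; fast
spiking interneurons (class `HVC_INT`, 7 ODEs) have a large delayed
rectifier so spikes undershoot rest, and no SK current. The calcium
currents use the Goldman–Hodgkin–Katz driving term
`Ca_ex · V / (1 − exp(2FV/RT))`; the T-type current
`ICaT = gCaT · aT∞³(V) · bT∞³(rT) · ghk(V)` is gated by a slow
availability variable `rT` that accumulates during hyperpolarization —
the biophysical substrate of delay-dependent priming. The H current uses
a two-component (fast/slow) activation. Synapses are first-order kinetic
AMPA and GABA_A conductances driven by a sigmoidal transmitter-release
function of presynaptic voltage (`ds/dt = ar·[T](Vpre)(1 − s) − ad·s`).

The full network wires 12 neurons: stimulus-selective inputs `A` and `B`,
the TRDL (`E1–E3`, `I1`, `I2`, with an `E3 → I1` feedback edge closing
the loop), the FFIC interneurons `I_A1–I_A3` converging on the `CSN`, and
a disinhibition interneuron `I_B` that silences the loop at the onset of
the second stimulus. Stimuli are DC pulses (default 50 ms, 200 pA) that
make the selective input neurons fire at 200 Hz.

## Worked example

```r
library(csnsim)

net <- build_full_network()
#> <network_model> 12 neurons, 18 synapses
#>   neurons: A(E) B(E) CSN(E) E1(E) E2(E) E3(E) I1(I) I2(I) I_A1(I) I_A2(I) I_A3(I) I_B(I)
#>   stimulus targets: S1=A  S2=B

rest <- find_rest_state(net)
res <- simulate(net, make_paired_protocol(150), dt_out = 0.05, rest = rest)
classify_combination(res)
#> <combination_outcome> condition 'paired': 5 spike(s), span 19.0 ms -> SUCCESS

integration_window_min(res)
#> [1] -89.78248

sw <- run_delay_sweep(delays = c(0, 50, 100, 150, 200, 260))
as.data.frame(sw)
#>   delay spikes success
#> 1     0      1   FALSE
#> 2    50      4    TRUE
#> 3   100      5    TRUE
#> 4   150      5    TRUE
#> 5   200      3   FALSE
#> 6   260      1   FALSE
```

The paired S1→S2 protocol at mid-range delays drives a successful
combination burst (4–12 spikes within 80 ms); the CSN is hyperpolarized
to about −89 mV during the inter-stimulus integration window; outside the
effective delay window — and for reversed, single or repeated stimuli
(`make_control_protocol()`) — the burst criterion fails. `run_heatmap()`,
`run_stimulus_sweeps()` and `run_oat_search()` reproduce the
conductance-interaction maps, stimulus-robustness grids and one-at-a-time
sensitivity ranges; `plot()` methods draw traces, tuning curves and
heatmaps. A thin command-line front end is installed at
`inst/cli/csn-netsim`.

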