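# Shared, lazily computed fixtures.  Building the default network and its
# resting state once keeps the suite fast; simulations are cached by key
# because several tests interrogate the same runs.

.fx <- new.env(parent = emptyenv())

fx <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, force(expr), envir = .fx)
  get(key, envir = .fx)
}

default_net <- function() fx("net", build_full_network())

default_rest <- function() fx("rest", find_rest_state(default_net()))

# Paired-protocol simulation on the default network, cached by delay.
sim_paired <- function(delay, dt_out = 0.05) {
  fx(paste0("paired_", delay, "_", dt_out),
     simulate(default_net(), make_paired_protocol(delay), dt_out = dt_out,
              rest = default_rest()))
}

sim_control <- function(condition) {
  fx(paste0("ctl_", condition),
     simulate(default_net(), make_control_protocol(condition),
              t_end = 800, dt_out = 0.05, rest = default_rest()))
}

# One-neuron network around a parameter set (isolated cell runs).
one_cell_net <- function(params, id = "A") {
  network_model(list(neuron_spec(id, params$neuron_class, "generic",
                                 params)),
                list(), stimulus_targets = list(S1 = id))
}

# Simulate an isolated cell under a single DC pulse.
sim_pulse <- function(params, amp, dur, t_end = 100 + dur + 250,
                      dt_out = 0.02) {
  net <- one_cell_net(params)
  pr <- make_paired_protocol(0, dur1 = dur, amp1 = amp)
  pr$pulses <- pr$pulses[1, , drop = FALSE]
  simulate(net, pr, t_end = t_end, dt_out = dt_out,
           rest = find_rest_state(net))
}
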