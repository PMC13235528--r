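# Network construction, validation, state layout and system assembly.

test_that("simple motifs have three neurons, two edges and the right
          receptor classes", {
  for (kind in c("dual_excitatory", "dual_inhibitory",
                 "inhibitory_excitatory")) {
    m <- build_simple_motif(kind)
    expect_length(m$neurons, 3)
    expect_length(m$synapses, 2)
    expect_true(all(vapply(m$synapses, `[[`, "", "post") == "CSN"))
  }
  ie <- build_simple_motif("inhibitory_excitatory")
  rec <- setNames(vapply(ie$synapses, `[[`, "", "receptor"),
                  vapply(ie$synapses, `[[`, "", "pre"))
  expect_equal(rec[["A"]], "GABA_A")
  expect_equal(rec[["B"]], "AMPA")
  de <- build_simple_motif("dual_excitatory")
  expect_true(all(vapply(de$synapses, `[[`, "", "receptor") == "AMPA"))
  expect_error(build_simple_motif("nonsense"))
})

test_that("the full network has 12 neurons and the 18 stated edges", {
  net <- default_net()
  expect_length(net$neurons, 12)
  expect_length(net$synapses, 18)
  tab <- connectivity_table(net)
  # every CSN afferent is GABA_A from an I_A interneuron or AMPA from B
  aff <- tab[tab$post == "CSN", ]
  expect_setequal(aff$pre, c("I_A1", "I_A2", "I_A3", "B"))
  expect_true(all(aff$receptor[grepl("^I_A", aff$pre)] == "GABA_A"))
  expect_equal(aff$receptor[aff$pre == "B"], "AMPA")
  # the loop-closing feedback edge and its receptor class
  expect_true(any(tab$pre == "E3" & tab$post == "I1" &
                    tab$receptor == "AMPA"))
  # rebound chain edges are inhibitory
  expect_true(any(tab$pre == "I1" & tab$post == "E2" &
                    tab$receptor == "GABA_A"))
  expect_true(any(tab$pre == "I2" & tab$post == "E3" &
                    tab$receptor == "GABA_A"))
  # no disinhibition of the first feedforward interneuron
  expect_false(any(tab$pre == "I_B" & tab$post == "I_A1"))
  expect_equal(net$stimulus_targets, list(S1 = "A", S2 = "B"))
})

test_that("network validation enforces endpoints and receptor consistency", {
  n <- list(neuron_spec("x", "HVC_X"), neuron_spec("i", "HVC_INT"))
  expect_error(network_model(n, list(synapse_spec("x", "gone", "AMPA", 5)),
                             list(S1 = "x")), "endpoint")
  expect_error(network_model(n, list(synapse_spec("i", "x", "AMPA", 5)),
                             list(S1 = "x")), "contradicts")
  expect_error(network_model(n, list(), list(S1 = "nope")), "target")
  expect_error(neuron_spec("c", "HVC_INT", role = "CSN"), "HVC_X")
  expect_error(build_full_network(list()), "missing")
})

test_that("state layout counts 8 ODEs per excitatory cell, 7 per
          interneuron, plus one per synapse", {
  net <- default_net()
  lay <- state_layout(net)
  classes <- vapply(net$neurons, `[[`, "", "neuron_class")
  expect_equal(lay$dim,
               8 * sum(classes == "HVC_X") + 7 * sum(classes == "HVC_INT") +
                 length(net$synapses))
  expect_equal(lay$dim, 8 * 6 + 7 * 6 + 18)
  expect_length(lay$state_names, lay$dim)
  expect_false(anyDuplicated(lay$state_names) > 0)
})

test_that("assembled derivative is near zero at rest and matches the
          compiled right-hand side", {
  net <- default_net()
  rest <- default_rest()
  sys <- assemble_system(net, NULL)
  expect_lt(max(abs(sys$derivs(0, rest))), 1e-6)
  expect_error(sys$derivs(0, rest[-1]), "dimension")
  # reference R derivatives vs compiled derivatives at perturbed states,
  # recovered through a single tiny Euler step of the compiled solver
  pr <- make_paired_protocol(50)
  sysp <- assemble_system(net, pr)
  pv <- csnsim:::network_parms(net, pr)
  set.seed(7)
  for (tpt in c(25, 125, 225)) {
    y <- rest + stats::rnorm(length(rest), 0, 0.005)
    vidx <- grep("\\.V$", names(y))
    y[vidx] <- y[vidx] + stats::rnorm(length(vidx), 0, 3)
    h <- 1e-6
    out <- deSolve::ode(y = y, times = c(tpt, tpt + h),
                        func = "csn_derivs", parms = pv,
                        dllname = "csnsim", initfunc = "csn_initmod",
                        method = "euler")
    dy_c <- (out[2, -1] - y) / h
    dy_r <- sysp$derivs(tpt, y)
    expect_equal(unname(dy_c), unname(dy_r), tolerance = 1e-4)
  }
})

test_that("removing an edge only changes the postsynaptic neuron's
          voltage derivative", {
  net <- default_net()
  rest <- default_rest()
  lay <- state_layout(net)
  set.seed(11)
  y <- rest
  vidx <- grep("\\.V$", names(y))
  y[vidx] <- y[vidx] + stats::rnorm(length(vidx), 0, 5)
  y[lay$syn_offset + 1] <- stats::runif(length(net$synapses), 0.1, 0.5)
  k <- which(vapply(net$synapses, function(s)
    s$pre == "I_A2" && s$post == "CSN", logical(1)))
  net2 <- net
  net2$synapses <- net$synapses[-k]
  d1 <- assemble_system(net, NULL)$derivs(0, y)
  d2 <- assemble_system(net2, NULL)$derivs(0, y[-(lay$syn_offset[k] + 1)])
  keep <- setdiff(seq_along(y), lay$syn_offset[k] + 1)
  changed <- which(abs(d1[keep] - d2) > 1e-12)
  expect_equal(lay$state_names[keep][changed], "CSN.V")
})

test_that("a zero-conductance network reproduces isolated single-cell
          trajectories", {
  cfg <- default_network_config()
  for (k in names(cfg$synapses)) cfg$synapses[[k]] <- 0
  net0 <- build_full_network(cfg)
  rest0 <- find_rest_state(net0)
  pr <- make_control_protocol("S1_only")
  res <- simulate(net0, pr, t_end = 300, dt_out = 0.05, rest = rest0)
  # isolated A neuron under the same pulse
  a_net <- one_cell_net(do.call(neuron_params,
                                c(list("HVC_X"), cfg$neurons$A)))
  a_res <- simulate(a_net, pr, t_end = 300, dt_out = 0.05,
                    rest = find_rest_state(a_net))
  expect_equal(voltage_trace(res, "A"), voltage_trace(a_res, "A"),
               tolerance = 1e-4)
  # unstimulated neurons stay at their isolated rest
  expect_lt(max(abs(voltage_trace(res, "CSN") - rest0[["CSN.V"]])), 0.5)
})
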