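# Ionic currents, single-neuron derivatives and the hallmark firing
# phenotypes of the two model classes.

test_that("T-current inactivation offset identity and full evaluation", {
  p <- neuron_params("HVC_X")
  # fully inactivated channel carries exactly zero current
  expect_identical(bT_inf(0, p$theta_b, p$sigma_b), 0)
  expect_identical(t_current(-50, 0, p), 0)
  # activation midpoint
  expect_equal(sigmoid_gate(p$theta_aT, p$theta_aT, p$sigma_aT), 0.5)
  # independent scalar arithmetic oracle at a stated point
  V <- -50; rT <- 0.6
  aT <- 1 / (1 + exp((V - p$theta_aT) / p$sigma_aT))
  bT <- 1 / (1 + exp((rT - p$theta_b) / p$sigma_b)) -
    1 / (1 + exp(-p$theta_b / p$sigma_b))
  drive <- p$Ca_ex * V / (1 - exp(p$two_F_over_RT * V))
  expect_equal(t_current(V, rT, p), p$gCaT * aT^3 * bT^3 * drive,
               tolerance = 1e-12)
})

test_that("H current is a convex combination with reversal at Vh", {
  p <- neuron_params("HVC_X")
  for (kr in c(0, 0.3, 1)) {
    p2 <- neuron_params("HVC_X", kr = kr)
    expect_equal(h_current(-80, 0.4, 0.4, p2), p2$gH * 0.4 * (-80 - p2$Vh))
  }
  expect_equal(h_current(p$Vh, 0.7, 0.2, p), 0)
  expect_equal(sigmoid_gate(p$theta_rf, p$theta_rf, p$sigma_rf), 0.5)
  expect_equal(csnsim:::rs_inf_of_V(p$theta_rs, p$theta_rs, p$sigma_rs),
               0.5)
})

test_that("membrane currents vanish at their reversal potentials", {
  p <- neuron_params("HVC_X")
  st <- initial_neuron_state(p, V = p$VK)
  cur <- membrane_currents(st, p)
  expect_equal(unname(cur[c("IK", "IA", "ISK")]), c(0, 0, 0))
  st2 <- initial_neuron_state(p, V = p$VL)
  expect_equal(unname(membrane_currents(st2, p)[["IL"]]), 0)
  # SK half-saturation at Ca = ks
  st3 <- initial_neuron_state(p, V = -50)
  st3[["Ca"]] <- p$ks
  expect_equal(membrane_currents(st3, p)[["ISK"]],
               p$gSK * 0.5 * (-50 - p$VK))
})

test_that("full current vector matches independent per-formula arithmetic", {
  p <- neuron_params("HVC_X")
  st <- c(V = -55, n = 0.3, h = 0.6, e = 0.4, rT = 0.5, rf = 0.2,
          rs = 0.1, Ca = 1.2)
  sig <- function(V, th, si) 1 / (1 + exp((V - th) / si))
  drive <- p$Ca_ex * (-55) / (1 - exp(p$two_F_over_RT * (-55)))
  expected <- c(
    IL = p$gL * (-55 - p$VL),
    IK = p$gK * 0.3^4 * (-55 - p$VK),
    INa = p$gNa * sig(-55, p$theta_m, p$sigma_m)^3 * 0.6 * (-55 - p$VNa),
    IA = p$gA * sig(-55, p$theta_a, p$sigma_a) * 0.4 * (-55 - p$VK),
    ICaL = p$gCaL * sig(-55, p$theta_s, p$sigma_s)^2 * drive,
    ICaT = p$gCaT * sig(-55, p$theta_aT, p$sigma_aT)^3 *
      (sig(0.5, p$theta_b, p$sigma_b) - sig(0, p$theta_b, p$sigma_b))^3 *
      drive,
    ISK = p$gSK * 1.2^2 / (1.2^2 + p$ks^2) * (-55 - p$VK),
    IH = p$gH * (p$kr * 0.2 + (1 - p$kr) * 0.1) * (-55 - p$Vh)
  )
  expect_equal(membrane_currents(st, p), expected, tolerance = 1e-12)
})

test_that("interneurons carry no SK current and a 7-dimensional state", {
  pint <- neuron_params("HVC_INT", gSK = 5)  # pinned back to zero
  expect_identical(pint$gSK, 0)
  st <- initial_neuron_state(pint)
  expect_length(st, 7)
  expect_equal(membrane_currents(st, pint)[["ISK"]], 0)
  expect_length(initial_neuron_state(neuron_params("HVC_X")), 8)
})

test_that("gate derivatives point inward at the boundaries of [0, 1]", {
  p <- neuron_params("HVC_X")
  for (V in c(-100, -70, -40, 0)) {
    st0 <- initial_neuron_state(p, V)
    st0[c("n", "h", "e", "rT", "rf", "rs")] <- 0
    d0 <- neuron_derivatives(st0, p)
    expect_true(all(d0[c("n", "h", "e", "rT", "rf", "rs")] >= 0))
    st1 <- initial_neuron_state(p, V)
    st1[c("n", "h", "e", "rT", "rf", "rs")] <- 1
    d1 <- neuron_derivatives(st1, p)
    expect_true(all(d1[c("n", "h", "e", "rT", "rf", "rs")] <= 0))
  }
  expect_error(neuron_derivatives(c(V = NaN, n = 0, h = 0, e = 0, rT = 0,
                                    rf = 0, rs = 0, Ca = 0), p),
               "non-finite")
})

test_that("the calcium pump relaxes calcium toward its basal level", {
  p <- neuron_params("HVC_X", gCaL = 0, gCaT = 0)
  st <- initial_neuron_state(p, -70)
  st[["Ca"]] <- p$bCa + 1
  expect_lt(neuron_derivatives(st, p)[["Ca"]], 0)
  st[["Ca"]] <- p$bCa
  expect_equal(neuron_derivatives(st, p)[["Ca"]], 0)
})

test_that("an isolated neuron has a true resting fixed point", {
  net <- one_cell_net(neuron_params("HVC_X"))
  rest <- find_rest_state(net)
  d <- assemble_system(net)$derivs(0, rest)
  expect_lt(max(abs(d)), 1e-6)
})

test_that("excitatory cells show sag, rebound and adaptation; interneuron
          spikes undershoot rest", {
  cfg <- default_network_config()
  # sag: under -100 pA the membrane dips then relaxes upward (H current)
  pcsn <- do.call(neuron_params, c(list("HVC_X"), cfg$neurons$CSN))
  res <- sim_pulse(pcsn, amp = -100, dur = 400)
  V <- voltage_trace(res, "A"); t <- res$time
  inp <- t >= 100 & t < 500
  sag <- V[max(which(inp))] - min(V[inp])
  expect_gt(sag, 2)
  # post-inhibitory rebound burst in the loop-neuron configuration
  pe2 <- do.call(neuron_params, c(list("HVC_X"), cfg$neurons$E2))
  res2 <- sim_pulse(pe2, amp = -150, dur = 50)
  reb <- detect_spikes(voltage_trace(res2, "A")[res2$time >= 150],
                       res2$time[res2$time >= 150])
  expect_gte(length(reb), 2)
  # depolarization-induced adaptation in the class template
  res3 <- sim_pulse(neuron_params("HVC_X"), amp = 200, dur = 300)
  isi <- diff(detect_spikes(voltage_trace(res3, "A"), res3$time))
  expect_gt(mean(tail(isi, 3)), 1.5 * mean(head(isi, 2)))
  # interneuron: interspike minima fall below the resting potential
  res4 <- sim_pulse(neuron_params("HVC_INT"), amp = 200, dur = 100)
  V4 <- voltage_trace(res4, "A"); t4 <- res4$time
  expect_gte(length(detect_spikes(V4, t4)), 5)
  expect_lt(min(V4[t4 > 110 & t4 < 200]), V4[1] - 2)
})
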