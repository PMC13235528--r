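# Ionic currents and single-neuron dynamics (reference R implementation;
# the compiled network right-hand side in src/ mirrors these formulas and is
# cross-checked against them in the test suite).

#' Low-threshold T-type calcium current
#'
#' \eqn{I_{CaT} = g_{CaT}\, a_{T\infty}^3(V)\, b_{T\infty}^3(r_T)\,
#' \mathrm{ghk}(V)} with instantaneous activation \eqn{a_T} and an
#' inactivation gate driven by the slow availability variable \eqn{r_T}
#' (de-inactivated by hyperpolarization).
#'
#' @param V Membrane potential (mV).
#' @param rT Availability variable in \[0, 1\].
#' @param params A [neuron_params()] object (uses the T-gate, calcium and
#'   GHK entries plus \code{gCaT} unless overridden).
#' @param gCaT Optional conductance override (nS).
#' @return Current (signed; negative = inward).
#' @export
t_current <- function(V, rT, params, gCaT = params$gCaT) {
  aT <- sigmoid_gate(V, params$theta_aT, params$sigma_aT)
  bT <- bT_inf(rT, params$theta_b, params$sigma_b)
  gCaT * aT^3 * bT^3 * ghk_drive(V, params$Ca_ex, params$two_F_over_RT)
}

#' Time derivative of the T-current availability variable
#'
#' \eqn{dr_T/dt = (r_{T\infty}(V) - r_T)/\tau_{rT}(V)}; the availability
#' rises during hyperpolarization with a slow voltage-dependent time
#' constant, which is what accumulates "priming" across the inter-stimulus
#' gap.
#'
#' @inheritParams t_current
#' @return d(rT)/dt in 1/ms.
#' @export
t_availability_derivative <- function(V, rT, params) {
  rinf <- sigmoid_gate(V, params$theta_rT, params$sigma_rT)
  tau <- tau_rT_of_V(V, params$tau_r0, params$tau_r1,
                     params$theta_rrT, params$sigma_rrT)
  (rinf - rT) / tau
}

#' Hyperpolarization-activated inward current
#'
#' Two-component form \eqn{I_H = g_H [k_r r_f + (1-k_r) r_s](V - V_h)} with
#' a fast (\code{rf}) and a slow (\code{rs}) activation gate.
#'
#' @param V Membrane potential (mV).
#' @param rf,rs Fast and slow activation gates in \[0, 1\].
#' @param params A [neuron_params()] object.
#' @param gH Optional conductance override (nS).
#' @return Current (signed; negative = inward below \code{Vh}).
#' @export
h_current <- function(V, rf, rs, params, gH = params$gH) {
  gH * (params$kr * rf + (1 - params$kr) * rs) * (V - params$Vh)
}

#' Gate derivatives of the H current
#'
#' @inheritParams h_current
#' @return List with \code{drf} and \code{drs} (1/ms).
#' @export
h_gate_derivatives <- function(V, rf, rs, params) {
  rf_inf <- sigmoid_gate(V, params$theta_rf, params$sigma_rf)
  rs_inf <- rs_inf_of_V(V, params$theta_rs, params$sigma_rs)
  list(drf = (rf_inf - rf) / tau_rf_of_V(V, params$prf),
       drs = (rs_inf - rs) / params$tau_rs)
}

#' Evaluate all membrane currents at one state
#'
#' Returns the labelled ionic current set \{IL, IK, INa, IA, ICaL, ICaT,
#' ISK, IH\} at a given state.  Gates m, a, s, aT, bT and the SK activation
#' are instantaneous functions of the state; n, h, e, rT, rf, rs are read
#' from the state vector.  For interneurons (class HVC_INT, no intracellular
#' calcium pool) ISK is reported as 0.
#'
#' @param state Named state vector as produced by [initial_neuron_state()].
#' @param params A [neuron_params()] object.
#' @return Named numeric vector of currents (pA; negative = inward).
#' @export
membrane_currents <- function(state, params) {
  V <- state[["V"]]
  p <- params
  IL <- p$gL * (V - p$VL)
  IK <- p$gK * state[["n"]]^4 * (V - p$VK)
  INa <- p$gNa * sigmoid_gate(V, p$theta_m, p$sigma_m)^3 * state[["h"]] *
    (V - p$VNa)
  IA <- p$gA * sigmoid_gate(V, p$theta_a, p$sigma_a) * state[["e"]] *
    (V - p$VK)
  ICaL <- p$gCaL * sigmoid_gate(V, p$theta_s, p$sigma_s)^2 *
    ghk_drive(V, p$Ca_ex, p$two_F_over_RT)
  ICaT <- t_current(V, state[["rT"]], p)
  if (p$neuron_class == "HVC_X") {
    Ca <- state[["Ca"]]
    ISK <- p$gSK * Ca^2 / (Ca^2 + p$ks^2) * (V - p$VK)
  } else {
    ISK <- 0
  }
  IH <- h_current(V, state[["rf"]], state[["rs"]], p)
  c(IL = IL, IK = IK, INa = INa, IA = IA, ICaL = ICaL, ICaT = ICaT,
    ISK = ISK, IH = IH)
}

#' Time derivative of a single neuron's state
#'
#' Membrane equation
#' \eqn{C_m dV/dt = -\sum I_{ionic} - I_{syn} + I_{app}}, first-order
#' relaxation for the dynamic gates, and calcium balance
#' \eqn{d[Ca]_i/dt = -f\,\varepsilon\,(I_{CaL}+I_{CaT}) -
#' k_{Ca}([Ca]_i - b_{Ca})} (the pump relaxes calcium toward its basal
#' level).
#'
#' @param state Named state vector.
#' @param params A [neuron_params()] object.
#' @param I_syn_total Total synaptic current onto this neuron (pA, signed).
#' @param I_app Applied (stimulus) current (pA; positive = depolarizing).
#' @return Named vector of state derivatives (same layout as \code{state}).
#' @export
neuron_derivatives <- function(state, params, I_syn_total = 0, I_app = 0) {
  if (any(!is.finite(state))) {
    stop("non-finite neuron state", call. = FALSE)
  }
  p <- params
  V <- state[["V"]]
  cur <- membrane_currents(state, p)
  dV <- (-sum(cur) - I_syn_total + I_app) / p$Cm
  hk <- h_gate_kinetics(V)
  dn <- (sigmoid_gate(V, p$theta_n, p$sigma_n) - state[["n"]]) / p$tau_n
  dh <- (hk$h_inf - state[["h"]]) / hk$tau_h
  de <- (sigmoid_gate(V, p$theta_e, p$sigma_e) - state[["e"]]) / p$tau_e
  drT <- t_availability_derivative(V, state[["rT"]], p)
  hg <- h_gate_derivatives(V, state[["rf"]], state[["rs"]], p)
  out <- c(V = dV, n = dn, h = dh, e = de, rT = drT,
           rf = hg$drf, rs = hg$drs)
  if (p$neuron_class == "HVC_X") {
    dCa <- -p$f * p$eps * (cur[["ICaL"]] + cur[["ICaT"]]) -
      p$kCa * (state[["Ca"]] - p$bCa)
    out <- c(out, Ca = dCa)
  }
  out
}
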