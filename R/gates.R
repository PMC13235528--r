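# Gating primitives shared by all ionic currents.

#' Boltzmann steady-state gating function
#'
#' Standard sigmoid activation/inactivation curve
#' \eqn{x_\infty(V) = 1/(1 + \exp((V - \theta)/\sigma))}.
#' A negative slope factor \code{sigma} gives a gate that opens with
#' depolarization (activation); a positive one gives a gate that opens with
#' hyperpolarization (inactivation / availability).
#'
#' @param V Membrane potential (mV). Vectorized.
#' @param theta Half-activation voltage (mV).
#' @param sigma Slope factor (mV); must be nonzero.
#' @return Open fraction in \[0, 1\].
#' @examples
#' sigmoid_gate(-35, theta = -35, sigma = -5)  # 0.5 at the midpoint
#' @export
sigmoid_gate <- function(V, theta, sigma) {
  if (any(sigma == 0)) {
    stop("slope factor 'sigma' must be nonzero", call. = FALSE)
  }
  1 / (1 + exp((V - theta) / sigma))
}

#' Sodium inactivation kinetics
#'
#' Rate-constant form of the fast sodium inactivation gate:
#' \eqn{\alpha_h(V) = 0.128 \exp(-(V+15)/18)},
#' \eqn{\beta_h(V) = 4/(1 + \exp(-(V+27)/5))},
#' with \eqn{h_\infty = \alpha_h/(\alpha_h+\beta_h)} and
#' \eqn{\tau_h = 1/(\alpha_h+\beta_h)} (ms).
#'
#' @param V Membrane potential (mV). Vectorized.
#' @return List with components \code{h_inf} (fraction) and \code{tau_h} (ms).
#' @export
h_gate_kinetics <- function(V) {
  alpha <- 0.128 * exp(-(V + 15) / 18)
  beta <- 4 / (1 + exp(-(V + 27) / 5))
  list(h_inf = alpha / (alpha + beta), tau_h = 1 / (alpha + beta))
}

#' Goldman-Hodgkin-Katz driving term for calcium currents
#'
#' Computes \eqn{[Ca]_{ex} \, V / (1 - \exp(kV))} with \eqn{k = 2F/RT} in
#' 1/mV.  The removable singularity at \eqn{V = 0} is handled with a series
#' expansion of \eqn{x/(e^x - 1)}; the limit is \eqn{-[Ca]_{ex}/k}.  The term
#' is negative over the physiological voltage range, so multiplying by a
#' positive conductance and open-gate fractions yields an inward (negative)
#' calcium current.
#'
#' @param V Membrane potential (mV). Vectorized.
#' @param Ca_ex External calcium scale (effective concentration units).
#' @param two_F_over_RT \eqn{2F/(RT)} in 1/mV; see [physical_constants()].
#' @return Driving term (signed), same length as \code{V}.
#' @export
ghk_drive <- function(V, Ca_ex, two_F_over_RT) {
  x <- two_F_over_RT * V
  out <- numeric(length(x))
  small <- abs(x) < 1e-4
  # V/(1 - e^x) = -(1/k) * x/(e^x - 1); series for x/(e^x-1) near 0
  if (any(small)) {
    xs <- x[small]
    out[small] <- -(1 / two_F_over_RT) *
      (1 - xs / 2 + xs^2 / 12 - xs^4 / 720)
  }
  if (any(!small)) {
    out[!small] <- V[!small] / (1 - exp(x[!small]))
  }
  Ca_ex * out
}

#' T-type calcium inactivation as a function of availability
#'
#' The instantaneous inactivation gate of the low-threshold calcium current
#' is driven by the slow availability variable \code{rT} rather than by
#' voltage: \eqn{b_\infty(r) = 1/(1+\exp((r-\theta_b)/\sigma_b)) -
#' 1/(1+\exp(-\theta_b/\sigma_b))}.  The offset subtraction makes
#' \eqn{b_\infty(0) = 0} exactly, so a fully inactivated channel carries no
#' current.
#'
#' @param rT Availability variable in \[0, 1\]. Vectorized.
#' @param theta_b Half point on the availability axis (dimensionless).
#' @param sigma_b Slope (dimensionless, negative for an increasing curve).
#' @return Open fraction of the inactivation gate.
#' @export
bT_inf <- function(rT, theta_b, sigma_b) {
  sigmoid_gate(rT, theta_b, sigma_b) - sigmoid_gate(0, theta_b, sigma_b)
}

# Voltage-dependent time constant of the T-current availability variable:
# tau_rT(V) = tau_r0 + tau_r1 / (1 + exp((V - theta_rrT)/sigma_rrT)).
tau_rT_of_V <- function(V, tau_r0, tau_r1, theta_rrT, sigma_rrT) {
  tau_r0 + tau_r1 * sigmoid_gate(V, theta_rrT, sigma_rrT)
}

# Time constant of the fast H-current component.  Linear-over-exponential
# term with a removable singularity at V = -70 mV plus an exponential tail;
# prf is a dimensionless scale.
tau_rf_of_V <- function(V, prf) {
  u <- V + 70
  lin <- ifelse(abs(u) < 1e-6, 7.4 * 0.8,
                -7.4 * u / (exp(u / -0.8) - 1))
  prf * (lin + 65 * exp((V + 56) / -23))
}

# Slow H-current component steady state, written with the explicit minus
# sign convention; sigma_rs < 0 gives hyperpolarization activation.
rs_inf_of_V <- function(V, theta_rs, sigma_rs) {
  1 / (1 + exp(-(V - theta_rs) / sigma_rs))
}
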