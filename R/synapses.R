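# First-order kinetic synapses with voltage-dependent transmitter release.
#
# Each synapse contributes one ODE for its open fraction s:
#   ds/dt = ar [T](V_pre) (1 - s) - ad s
# with a sigmoidal release function [T] of the presynaptic voltage.  AMPA
# and GABA_A differ only in their rate constants and reversal potential.

.receptor_defaults <- list(
  AMPA = list(ar = 1.1, ad = 0.19, Vrev = 0),
  GABA_A = list(ar = 5, ad = 0.18, Vrev = -95)
)

#' Specify one synapse
#'
#' @param pre,post Neuron ids (labels used in the network model).
#' @param receptor \code{"AMPA"} or \code{"GABA_A"}; fixes the kinetic rates
#'   and reversal potential unless overridden.
#' @param g Maximal conductance (nS).
#' @param Vrev Reversal potential (mV); default 0 for AMPA, -95 for GABA_A.
#' @param ar,ad Rise and decay rate constants (1/ms with \[T\]
#'   dimensionless).
#' @param Tmax,Kp,VT Transmitter release constants: maximal release,
#'   slope (mV) and half-release presynaptic voltage (mV).
#' @return Object of class \code{"synapse_spec"}.
#' @export
synapse_spec <- function(pre, post, receptor = c("AMPA", "GABA_A"), g,
                         Vrev = NULL, ar = NULL, ad = NULL,
                         Tmax = 1, Kp = 5, VT = 2) {
  receptor <- match.arg(receptor)
  def <- .receptor_defaults[[receptor]]
  spec <- list(pre = pre, post = post, receptor = receptor, g = g,
               Vrev = if (is.null(Vrev)) def$Vrev else Vrev,
               ar = if (is.null(ar)) def$ar else ar,
               ad = if (is.null(ad)) def$ad else ad,
               Tmax = Tmax, Kp = Kp, VT = VT)
  if (spec$g < 0) stop("synaptic conductance must be >= 0", call. = FALSE)
  if (spec$ar <= 0 || spec$ad <= 0) {
    stop("synaptic rates ar, ad must be positive", call. = FALSE)
  }
  structure(spec, class = "synapse_spec")
}

#' Transmitter concentration released by a presynaptic neuron
#'
#' \eqn{[T](V_{pre}) = T_{max} / (1 + \exp(-(V_{pre} - V_T)/K_p))}:
#' essentially zero at rest and saturating at \code{Tmax} during a
#' presynaptic spike.
#'
#' @param V_pre Presynaptic membrane potential (mV). Vectorized.
#' @param spec A [synapse_spec()] (uses \code{Tmax}, \code{Kp}, \code{VT}).
#' @return Concentration in (0, Tmax).
#' @export
transmitter_concentration <- function(V_pre, spec) {
  spec$Tmax / (1 + exp(-(V_pre - spec$VT) / spec$Kp))
}

#' Time derivative of the synaptic gating variable
#'
#' @param s Open fraction in \[0, 1\].
#' @param T_conc Transmitter concentration (same units as \code{Tmax}).
#' @param spec A [synapse_spec()].
#' @return ds/dt (1/ms).
#' @export
synapse_gate_derivative <- function(s, T_conc, spec) {
  spec$ar * T_conc * (1 - s) - spec$ad * s
}

#' Postsynaptic current through one synapse
#'
#' \eqn{I = g\, s\, (V_{post} - V_{rev})}; positive (outward,
#' hyperpolarizing) for GABA_A above its reversal, negative (inward) for
#' AMPA below 0 mV.
#'
#' @param s Open fraction in \[0, 1\].
#' @param V_post Postsynaptic membrane potential (mV).
#' @param spec A [synapse_spec()].
#' @return Current (pA, signed).
#' @export
synaptic_current <- function(s, V_post, spec) {
  spec$g * s * (V_post - spec$Vrev)
}

#' @export
print.synapse_spec <- function(x, ...) {
  cat(sprintf("<synapse_spec> %s -> %s  %s  g=%g nS  Vrev=%g mV  ar=%g ad=%g\n",
              x$pre, x$post, x$receptor, x$g, x$Vrev, x$ar, x$ad))
  invisible(x)
}
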