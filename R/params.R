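# Parameter containers for single neurons.
#
# Units convention throughout the package: mV, ms, nS, pA, pF
# (nS * mV = pA; pA / pF = mV/ms).  Intracellular calcium is carried in
# arbitrary concentration units (effectively micromolar) that cancel in the
# SK activation ratio; the GHK driving term carries an effective external
# calcium scale Ca_ex so that nanosiemens-scale T- and L-type conductances
# produce currents in pA.

#' Physical constants for the GHK-form calcium currents
#'
#' @param temperature_C Temperature in degrees Celsius (songbird body
#'   temperature by default).
#' @return List with \code{two_F_over_RT} (1/mV) and the temperature used.
#' @export
physical_constants <- function(temperature_C = 40) {
  FARADAY <- 96485.332  # C/mol
  RGAS <- 8.314462      # J/(mol K)
  TK <- temperature_C + 273.15
  list(two_F_over_RT = 2 * FARADAY / (RGAS * TK) / 1000,
       temperature_C = temperature_C)
}

# Canonical flat ordering of the per-neuron numeric parameters.  This order
# is shared with the compiled right-hand side; do not reorder.
.neuron_par_names <- c(
  "Cm",
  "gNa", "gK", "gA", "gL", "gCaL", "gCaT", "gSK", "gH",
  "VNa", "VK", "VL", "Vh",
  "theta_m", "sigma_m",
  "theta_n", "sigma_n", "tau_n",
  "theta_e", "sigma_e", "tau_e",
  "theta_a", "sigma_a",
  "theta_s", "sigma_s",
  "theta_aT", "sigma_aT",
  "theta_b", "sigma_b",
  "theta_rT", "sigma_rT",
  "tau_r0", "tau_r1", "theta_rrT", "sigma_rrT",
  "kr", "prf", "theta_rf", "sigma_rf",
  "theta_rs", "sigma_rs", "tau_rs",
  "f", "eps", "kCa", "bCa", "ks",
  "Ca_ex", "two_F_over_RT"
)

# Class templates.  The excitatory template reproduces the hallmark
# projection-neuron phenotype (sag under hyperpolarization, post-inhibitory
# rebound, calcium-dependent spike-frequency adaptation); the interneuron
# template is a fast-spiking cell with a large delayed rectifier so that
# spikes undershoot rest, no SK current and negligible rebound machinery.
.neuron_templates <- function() {
  pc <- physical_constants()
  hvc_x <- list(
    Cm = 100,
    gNa = 450, gK = 130, gA = 5, gL = 2, gCaL = 0.4, gCaT = 0.4,
    gSK = 6, gH = 4,
    VNa = 55, VK = -90, VL = -70, Vh = -30,
    theta_m = -35, sigma_m = -5,
    theta_n = -33, sigma_n = -5, tau_n = 1,
    theta_e = -60, sigma_e = 5, tau_e = 20,
    theta_a = -20, sigma_a = -10,
    theta_s = -30, sigma_s = -5,
    theta_aT = -65, sigma_aT = -7.8,
    theta_b = 0.4, sigma_b = -0.1,
    theta_rT = -80, sigma_rT = 5,
    tau_r0 = 50, tau_r1 = 100, theta_rrT = -80, sigma_rrT = 5,
    kr = 0.6, prf = 0.3, theta_rf = -95, sigma_rf = 8,
    theta_rs = -95, sigma_rs = -12, tau_rs = 300,
    f = 0.1, eps = 0.04, kCa = 0.02, bCa = 0.05, ks = 0.5,
    Ca_ex = 10, two_F_over_RT = pc$two_F_over_RT
  )
  hvc_int <- hvc_x
  hvc_int[c("gK", "gA", "gL", "gCaL", "gCaT", "gSK", "gH", "VL",
            "theta_n", "tau_n")] <-
    list(250, 0, 3, 0.05, 0.1, 0, 1, -52, -40, 1.5)
  list(HVC_X = hvc_x, HVC_INT = hvc_int)
}

#' Construct a neuron parameter set
#'
#' Builds the full parameter list for one model neuron, starting from the
#' class template (\code{"HVC_X"} excitatory projection neuron or
#' \code{"HVC_INT"} fast-spiking interneuron) and applying any overrides.
#' Interneurons carry no SK current: \code{gSK} is pinned to 0 for class
#' \code{"HVC_INT"}.
#'
#' @param neuron_class \code{"HVC_X"} or \code{"HVC_INT"}.
#' @param ... Named numeric overrides of template entries (e.g.
#'   \code{gCaT = 0.8}).
#' @return Object of class \code{"neuron_params"}: a named list with all
#'   canonical parameter entries plus \code{neuron_class}.
#' @export
neuron_params <- function(neuron_class = c("HVC_X", "HVC_INT"), ...) {
  neuron_class <- match.arg(neuron_class)
  p <- .neuron_templates()[[neuron_class]]
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(p))
    if (length(bad)) {
      stop("unknown neuron parameter(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    p[names(dots)] <- dots
  }
  if (neuron_class == "HVC_INT") p$gSK <- 0
  p$neuron_class <- neuron_class
  validate_neuron_params(p)
  structure(p, class = "neuron_params")
}

validate_neuron_params <- function(p) {
  conds <- c("gNa", "gK", "gA", "gL", "gCaL", "gCaT", "gSK", "gH")
  vals <- unlist(p[conds])
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("conductances must be finite and nonnegative", call. = FALSE)
  }
  if (p$Cm <= 0) stop("Cm must be positive", call. = FALSE)
  sig <- unlist(p[grep("^sigma_", .neuron_par_names, value = TRUE)])
  if (any(sig == 0)) stop("slope factors must be nonzero", call. = FALSE)
  taus <- unlist(p[c("tau_n", "tau_e", "tau_r0", "tau_rs")])
  if (any(taus <= 0)) stop("time constants must be positive", call. = FALSE)
  if (p$tau_r0 + p$tau_r1 <= 0) {
    stop("tau_r0 + tau_r1 must be positive", call. = FALSE)
  }
  if (p$kr < 0 || p$kr > 1) stop("kr must lie in [0, 1]", call. = FALSE)
  with(p, {
    if (f <= 0 || f > 1 || eps <= 0 || kCa <= 0 || bCa <= 0 || ks <= 0 ||
        Ca_ex <= 0 || two_F_over_RT <= 0) {
      stop("calcium handling parameters must be positive (0 < f <= 1)",
           call. = FALSE)
    }
  })
  invisible(p)
}

# Flatten a neuron_params object into the canonical numeric vector used by
# the compiled right-hand side.
pack_neuron_params <- function(p) {
  as.numeric(unlist(p[.neuron_par_names]))
}

# Names of the dynamic state variables per class.  HVC_X carries
# intracellular calcium (8 ODEs); HVC_INT does not (7 ODEs).
neuron_state_names <- function(neuron_class) {
  base <- c("V", "n", "h", "e", "rT", "rf", "rs")
  if (neuron_class == "HVC_X") c(base, "Ca") else base
}

#' Default initial state for a neuron
#'
#' Gates are started at their steady-state values for the given voltage and
#' calcium at its basal level; the subsequent rest-state relaxation in
#' [find_rest_state()] removes any residual transient.
#'
#' @param params A [neuron_params()] object.
#' @param V Starting membrane potential (mV).
#' @return Named numeric state vector (length 8 for HVC_X, 7 for HVC_INT).
#' @export
initial_neuron_state <- function(params, V = -70) {
  hk <- h_gate_kinetics(V)
  st <- c(
    V = V,
    n = sigmoid_gate(V, params$theta_n, params$sigma_n),
    h = hk$h_inf,
    e = sigmoid_gate(V, params$theta_e, params$sigma_e),
    rT = sigmoid_gate(V, params$theta_rT, params$sigma_rT),
    rf = sigmoid_gate(V, params$theta_rf, params$sigma_rf),
    rs = rs_inf_of_V(V, params$theta_rs, params$sigma_rs)
  )
  if (params$neuron_class == "HVC_X") st <- c(st, Ca = params$bCa)
  st
}

#' @export
print.neuron_params <- function(x, ...) {
  cat("<neuron_params> class", x$neuron_class, "\n")
  cat(sprintf("  Cm = %g pF; gNa=%g gK=%g gA=%g gL=%g gCaL=%g gCaT=%g gSK=%g gH=%g nS\n",
              x$Cm, x$gNa, x$gK, x$gA, x$gL, x$gCaL, x$gCaT, x$gSK, x$gH))
  cat(sprintf("  VNa=%g VK=%g VL=%g Vh=%g mV\n", x$VNa, x$VK, x$VL, x$Vh))
  invisible(x)
}
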