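# Canonical model configuration, serialization and run manifests.
#
# The configuration holds everything that defines a run: per-neuron
# parameter overrides on top of the class templates, per-edge synaptic
# conductances, motif definitions, solver options and stimulus defaults.
# The shipped file inst/extdata/default_network.yaml mirrors
# default_network_config() and the test suite keeps the two in sync.

#' Default network configuration
#'
#' The calibrated default parameter set of the layered delay-loop network:
#' per-neuron overrides of the class templates (notably the CSN's
#' \code{gCaT} = 0.4 nS and \code{gH} = 6 nS and the strong rebound
#' machinery of the loop neurons E2/E3), the 18 synaptic conductances, the
#' three simple-motif configurations, stimulus defaults (50 ms, 200 pA)
#' and solver settings.
#'
#' @return Nested configuration list.
#' @export
default_network_config <- function() {
  list(
    neurons = list(
      # stimulus-selective drivers and the loop entry relay: small, fast,
      # weakly adapting cells tuned to fire at 200 Hz under a 200 pA pulse
      A = list(Cm = 50, gL = 2.5, gCaT = 0.1, gSK = 0.5, gH = 1),
      B = list(Cm = 50, gL = 2.5, gCaT = 0.1, gSK = 0.5, gH = 1),
      E1 = list(Cm = 50, gL = 2.5, gCaT = 0.1, gSK = 0.5, gH = 1),
      # the combination-sensitive output neuron: weak T conductance with a
      # steep activation gate so the low-threshold calcium burst ignites
      # only when rebound and AMPA drive coincide; slow availability
      # kinetics integrate inhibition across the delay
      CSN = list(gCaT = 0.4, gH = 6, gSK = 10, gCaL = 1.5,
                 Ca_ex = 50, eps = 0.01, ks = 2,
                 theta_aT = -60, sigma_aT = -4.5,
                 theta_rT = -78, sigma_rT = 4,
                 tau_r0 = 50, tau_r1 = 30, theta_rrT = -70, sigma_rrT = -5,
                 theta_rf = -95, sigma_rf = 8, prf = 0.8,
                 theta_rs = -95),
      # delay-loop rebound neurons: strong T and H conductances, fast
      # de-inactivation, and slow calcium clearance so successive rebound
      # cycles run down and the loop dies out
      E2 = list(Cm = 50, gCaT = 4, gH = 10, gSK = 3, ks = 2,
                theta_aT = -67, theta_rf = -90, theta_rs = -90,
                tau_r0 = 20, tau_r1 = 30, theta_rrT = -70, sigma_rrT = -5,
                kCa = 0.013, eps = 0.015),
      E3 = list(Cm = 50, gCaT = 4, gH = 10, gSK = 3, ks = 2,
                theta_aT = -67, theta_rf = -90, theta_rs = -90,
                tau_r0 = 20, tau_r1 = 30, theta_rrT = -70, sigma_rrT = -5,
                kCa = 0.013, eps = 0.015),
      I1 = list(), I2 = list(),
      I_A1 = list(), I_A2 = list(), I_A3 = list(),
      I_B = list()
    ),
    synapses = list(
      "A->E1" = 20,
      "E1->I1" = 25, "I1->E2" = 25,
      "E2->I2" = 25, "I2->E3" = 25,
      "E3->I1" = 15,
      "E1->I_A1" = 25, "E2->I_A2" = 25, "E3->I_A3" = 25,
      "I_A1->CSN" = 20, "I_A2->CSN" = 20, "I_A3->CSN" = 20,
      "B->CSN" = 3.2, "B->I_B" = 25,
      "I_B->I1" = 25, "I_B->I2" = 25,
      "I_B->I_A2" = 25, "I_B->I_A3" = 25
    ),
    motifs = list(
      # temporal summation: two subthreshold excitatory inputs; a leaky
      # integrator CSN fires only when the EPSPs overlap in time
      dual_excitatory = list(
        a_inhibitory = FALSE, b_inhibitory = FALSE,
        a_params = list(Cm = 50, gL = 2.5, gCaT = 0.1, gSK = 0.5, gH = 1),
        b_params = list(Cm = 50, gL = 2.5, gCaT = 0.1, gSK = 0.5, gH = 1),
        csn_params = list(gCaT = 0.1, gH = 2, gSK = 2, gL = 2),
        gA_CSN = 2, gB_CSN = 2
      ),
      # dual post-inhibitory rebound: converging inhibition onto a
      # strongly rebounding CSN (loop-neuron phenotype)
      dual_inhibitory = list(
        a_inhibitory = TRUE, b_inhibitory = TRUE,
        a_params = list(), b_params = list(),
        csn_params = list(Cm = 50, gCaT = 4, gH = 10, gSK = 3, ks = 2,
                          theta_aT = -67, theta_rf = -90, theta_rs = -90,
                          tau_r0 = 20, tau_r1 = 30, theta_rrT = -70,
                          sigma_rrT = -5, kCa = 0.013, eps = 0.015),
        gA_CSN = 20, gB_CSN = 20
      ),
      # postsynaptic facilitation: inhibitory priming then excitatory
      # readout; the CSN is the full-network cell with faster availability
      # build-up because priming here lasts only one stimulus duration
      inhibitory_excitatory = list(
        a_inhibitory = TRUE, b_inhibitory = FALSE,
        a_params = list(),
        b_params = list(Cm = 50, gL = 2.5, gCaT = 0.1, gSK = 0.5, gH = 1),
        csn_params = list(gCaT = 0.4, gH = 6, gSK = 8, gCaL = 1.5,
                          Ca_ex = 60, eps = 0.01, ks = 2,
                          theta_aT = -60, sigma_aT = -4.5,
                          theta_rT = -78, sigma_rT = 4,
                          tau_r0 = 25, tau_r1 = 30, theta_rrT = -70,
                          sigma_rrT = -5,
                          theta_rf = -95, sigma_rf = 8, prf = 0.8,
                          theta_rs = -95),
        gA_CSN = 20, gB_CSN = 3.6
      )
    ),
    stimulus = list(duration = 50, amplitude = 200),
    solver = list(method = "lsoda", rtol = 1e-6, atol = 1e-8,
                  dt_out = 0.01)
  )
}

.config_top_keys <- c("neurons", "synapses", "motifs", "stimulus", "solver")

#' Validate a configuration list
#'
#' Rejects unknown top-level keys, unknown neuron ids or edges, negative
#' conductances and malformed solver blocks; missing entries are filled
#' from [default_network_config()].
#'
#' @param config Configuration list (possibly partial).
#' @return The validated, completed configuration.
#' @export
validate_config <- function(config) {
  def <- default_network_config()
  bad <- setdiff(names(config), .config_top_keys)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- def
  for (k in names(config)) {
    if (k %in% c("neurons", "synapses", "motifs")) {
      extra <- setdiff(names(config[[k]]), names(def[[k]]))
      if (length(extra)) {
        stop("unknown ", k, " entr", if (length(extra) > 1) "ies: " else "y: ",
             paste(extra, collapse = ", "), call. = FALSE)
      }
      for (id in names(config[[k]])) {
        if (k == "synapses") {
          out[[k]][[id]] <- config[[k]][[id]]
        } else if (k == "neurons") {
          out[[k]][[id]] <- utils::modifyList(def[[k]][[id]],
                                              config[[k]][[id]])
        } else {
          out[[k]][[id]] <- utils::modifyList(def[[k]][[id]],
                                              config[[k]][[id]])
        }
      }
    } else {
      out[[k]] <- utils::modifyList(def[[k]], config[[k]])
    }
  }
  g <- unlist(out$synapses)
  if (any(g < 0)) {
    stop("negative synaptic conductance in config: ",
         paste(names(g)[g < 0], collapse = ", "), call. = FALSE)
  }
  for (id in names(out$neurons)) {
    v <- unlist(out$neurons[[id]])
    cond <- grepl("^g", names(v))
    if (any(v[cond] < 0)) {
      stop("negative conductance for neuron ", id, call. = FALSE)
    }
  }
  if (out$solver$rtol <= 0 || out$solver$atol <= 0 ||
      out$solver$dt_out <= 0) {
    stop("solver tolerances and output step must be positive",
         call. = FALSE)
  }
  out
}

#' Load a configuration from a YAML file
#'
#' @param path Path to a YAML configuration file.
#' @return Validated configuration list (defaults filled in).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' Save a configuration to a YAML file
#'
#' @param config Configuration list.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(config, path, precision = 15)
  invisible(path)
}

#' Hash of a configuration
#'
#' Order-independent FNV-1a hash over the canonicalized (validated,
#' default-completed) configuration; identifies a run's inputs in
#' manifests.
#'
#' @param config Configuration list.
#' @return Hex string.
#' @export
config_hash <- function(config) {
  config <- validate_config(config)
  bytes <- as.integer(serialize(config, NULL, version = 2))
  # FNV-1a, 32 bit, dependency-free; the xor only touches the low byte so
  # it is computed on that byte alone to stay within integer range
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- (h - low) + bitwXor(as.integer(low), b)
    # 32-bit modular multiply in 16-bit halves to stay exact in doubles
    h <- (h %% 65536 * p + ((h %/% 65536 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Apply a parameter-path override to a configuration
#'
#' Paths address the quantities the experiment drivers can sweep:
#' \code{"<neuron>.<param>"} for an intrinsic parameter (e.g.
#' \code{"CSN.gCaT"}) and \code{"syn.<pre>-><post>"} for a synaptic
#' conductance (e.g. \code{"syn.B->CSN"}).
#'
#' @param config Configuration list.
#' @param path Parameter path.
#' @param value New numeric value.
#' @return Modified configuration.
#' @export
config_set <- function(config, path, value) {
  if (startsWith(path, "syn.")) {
    key <- substring(path, 5)
    if (!key %in% names(config$synapses)) {
      stop("unknown synapse path: ", path, call. = FALSE)
    }
    config$synapses[[key]] <- value
    return(config)
  }
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2 || !parts[1] %in% names(config$neurons)) {
    stop("unknown parameter path: ", path, call. = FALSE)
  }
  config$neurons[[parts[1]]][[parts[2]]] <- value
  config
}
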