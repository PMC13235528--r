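# Declarative network construction: simple three-neuron motifs and the
# full layered architecture (transient reverberatory delay loop, TRDL, plus
# feedforward inhibitory convergence, FFIC), and compilation of a network
# description into one coupled ODE system.

#' Specify one neuron in a network
#'
#' @param id Unique label.
#' @param neuron_class \code{"HVC_X"} or \code{"HVC_INT"}.
#' @param role Functional role label (e.g. \code{"CSN"}, \code{"E1"},
#'   \code{"I_A2"}, \code{"A_selective"}); purely descriptive.
#' @param params A [neuron_params()] object; defaults to the class template.
#' @return Object of class \code{"neuron_spec"}.
#' @export
neuron_spec <- function(id, neuron_class = c("HVC_X", "HVC_INT"),
                        role = "generic", params = NULL) {
  neuron_class <- match.arg(neuron_class)
  if (is.null(params)) params <- neuron_params(neuron_class)
  stopifnot(inherits(params, "neuron_params"))
  if (params$neuron_class != neuron_class) {
    stop("params class does not match neuron_class", call. = FALSE)
  }
  if (identical(role, "CSN") && neuron_class != "HVC_X") {
    stop("the combination-sensitive neuron must be of class HVC_X",
         call. = FALSE)
  }
  structure(list(id = id, neuron_class = neuron_class, role = role,
                 params = params), class = "neuron_spec")
}

#' Assemble a network model
#'
#' Bundles neurons, directed synapses and the stimulus-target map, and
#' validates consistency: all edge endpoints must exist, and the receptor
#' class of every edge must match the presynaptic neuron class (excitatory
#' HVC_X -> AMPA, interneuron HVC_INT -> GABA_A).
#'
#' @param neurons List of [neuron_spec()] objects.
#' @param synapses List of [synapse_spec()] objects.
#' @param stimulus_targets Named list mapping stimulus labels (\code{"S1"},
#'   \code{"S2"}) to character vectors of neuron ids.
#' @return Object of class \code{"network_model"}.
#' @export
network_model <- function(neurons, synapses, stimulus_targets) {
  ids <- vapply(neurons, `[[`, "", "id")
  if (anyDuplicated(ids)) stop("duplicate neuron ids", call. = FALSE)
  names(neurons) <- ids
  classes <- vapply(neurons, `[[`, "", "neuron_class")
  for (s in synapses) {
    if (!s$pre %in% ids || !s$post %in% ids) {
      stop("synapse endpoint not in neuron list: ", s$pre, " -> ", s$post,
           call. = FALSE)
    }
    expected <- if (classes[[s$pre]] == "HVC_X") "AMPA" else "GABA_A"
    if (s$receptor != expected) {
      stop(sprintf(
        "receptor %s on edge %s -> %s contradicts presynaptic class %s",
        s$receptor, s$pre, s$post, classes[[s$pre]]), call. = FALSE)
    }
  }
  for (tgt in unlist(stimulus_targets)) {
    if (!tgt %in% ids) {
      stop("stimulus target not in neuron list: ", tgt, call. = FALSE)
    }
  }
  structure(list(neurons = neurons, synapses = synapses,
                 stimulus_targets = stimulus_targets),
            class = "network_model")
}

#' State-vector layout of a network
#'
#' Maps each neuron to its slice of the global state vector (8 states for
#' HVC_X, 7 for HVC_INT) and each synapse to its gating-variable index.
#'
#' @param model A [network_model()].
#' @return List with \code{dim} (total dimension), \code{neuron_offset}
#'   (named integer vector of 0-based offsets), \code{neuron_dim},
#'   \code{syn_offset} (0-based indices of the synaptic gates) and
#'   \code{state_names}.
#' @export
state_layout <- function(model) {
  ids <- names(model$neurons)
  dims <- vapply(model$neurons, function(n) {
    if (n$neuron_class == "HVC_X") 8L else 7L
  }, integer(1))
  offsets <- cumsum(c(0L, dims[-length(dims)]))
  names(offsets) <- ids
  n_states <- sum(dims)
  syn_offset <- n_states + seq_along(model$synapses) - 1L
  nm <- unlist(lapply(ids, function(id) {
    paste(id, neuron_state_names(model$neurons[[id]]$neuron_class),
          sep = ".")
  }))
  syn_nm <- vapply(model$synapses, function(s) {
    paste0("s.", s$pre, ".", s$post)
  }, "")
  list(dim = n_states + length(model$synapses),
       neuron_offset = offsets, neuron_dim = dims,
       syn_offset = syn_offset, state_names = c(nm, syn_nm))
}

#' Build one of the three simple convergence motifs
#'
#' Three neurons (an S1-driven input, an S2-driven input and the CSN) and
#' two synapses onto the CSN:
#' \describe{
#'   \item{dual_excitatory}{temporal summation; both inputs excitatory
#'     (AMPA).}
#'   \item{dual_inhibitory}{dual post-inhibitory rebound; both inputs
#'     inhibitory (GABA_A).}
#'   \item{inhibitory_excitatory}{postsynaptic facilitation; the S1-driven
#'     interneuron inhibits the CSN, the S2-driven neuron excites it.}
#' }
#'
#' @param kind Motif kind (see above).
#' @param config Optional configuration list as in
#'   [default_network_config()]; entries \code{motif_csn} and
#'   \code{motif_synapses} override CSN parameters and edge conductances.
#' @return A [network_model()] with neurons \code{A}, \code{B}, \code{CSN}.
#' @export
build_simple_motif <- function(kind = c("dual_excitatory", "dual_inhibitory",
                                        "inhibitory_excitatory"),
                               config = default_network_config()) {
  kind <- match.arg(kind)
  mc <- config$motifs[[kind]]
  a_class <- if (mc$a_inhibitory) "HVC_INT" else "HVC_X"
  b_class <- if (mc$b_inhibitory) "HVC_INT" else "HVC_X"
  neurons <- list(
    neuron_spec("A", a_class, "A_selective",
                do.call(neuron_params, c(list(a_class), mc$a_params))),
    neuron_spec("B", b_class, "B_selective",
                do.call(neuron_params, c(list(b_class), mc$b_params))),
    neuron_spec("CSN", "HVC_X", "CSN",
                do.call(neuron_params, c(list("HVC_X"), mc$csn_params)))
  )
  syn <- list(
    synapse_spec("A", "CSN", if (mc$a_inhibitory) "GABA_A" else "AMPA",
                 g = mc$gA_CSN),
    synapse_spec("B", "CSN", if (mc$b_inhibitory) "GABA_A" else "AMPA",
                 g = mc$gB_CSN)
  )
  network_model(neurons, syn,
                stimulus_targets = list(S1 = "A", S2 = "B"))
}

#' Build the full layered delay-loop network
#'
#' Twelve neurons: the stimulus-selective excitatory inputs \code{A} and
#' \code{B}; the TRDL (\code{E1}-\code{E3} excitatory, \code{I1},
#' \code{I2} inhibitory) with the \code{E3 -> I1} feedback edge closing the
#' loop; the FFIC interneurons \code{I_A1}-\code{I_A3} relaying sequential
#' loop activity into inhibition of the \code{CSN}; and the
#' disinhibition interneuron \code{I_B}, driven by \code{B}, which silences
#' \code{I1}, \code{I2}, \code{I_A2} and \code{I_A3} at S2 onset.  18
#' directed synapses in total.
#'
#' @param config Configuration list as from [default_network_config()];
#'   \code{config$neurons} gives per-neuron parameter overrides and
#'   \code{config$synapses} the edge conductances.
#' @return A [network_model()] with 12 neurons and 18 synapses.
#' @export
build_full_network <- function(config = default_network_config()) {
  nc <- config$neurons
  roles <- list(
    A = "HVC_X", B = "HVC_X", CSN = "HVC_X",
    E1 = "HVC_X", E2 = "HVC_X", E3 = "HVC_X",
    I1 = "HVC_INT", I2 = "HVC_INT",
    I_A1 = "HVC_INT", I_A2 = "HVC_INT", I_A3 = "HVC_INT",
    I_B = "HVC_INT"
  )
  neurons <- lapply(names(roles), function(id) {
    if (is.null(nc[[id]])) {
      stop("config missing a parameter block for neuron ", id,
           call. = FALSE)
    }
    neuron_spec(id, roles[[id]], role = id,
                params = do.call(neuron_params,
                                 c(list(roles[[id]]), nc[[id]])))
  })
  sc <- config$synapses
  edge <- function(pre, post) {
    receptor <- if (roles[[pre]] == "HVC_X") "AMPA" else "GABA_A"
    key <- paste0(pre, "->", post)
    if (is.null(sc[[key]])) {
      stop("config missing synaptic conductance for edge ", key,
           call. = FALSE)
    }
    synapse_spec(pre, post, receptor, g = sc[[key]])
  }
  synapses <- list(
    edge("A", "E1"),
    edge("E1", "I1"), edge("I1", "E2"),
    edge("E2", "I2"), edge("I2", "E3"),
    edge("E3", "I1"),                      # loop-closing feedback
    edge("E1", "I_A1"), edge("E2", "I_A2"), edge("E3", "I_A3"),
    edge("I_A1", "CSN"), edge("I_A2", "CSN"), edge("I_A3", "CSN"),
    edge("B", "CSN"), edge("B", "I_B"),
    edge("I_B", "I1"), edge("I_B", "I2"),
    edge("I_B", "I_A2"), edge("I_B", "I_A3")
  )
  network_model(neurons, synapses,
                stimulus_targets = list(S1 = "A", S2 = "B"))
}

#' Compile a network plus protocol into a derivative function
#'
#' Returns a plain-R derivative function over the global state vector,
#' evaluating all neuron and synapse ODEs with per-neuron total synaptic
#' current and the time-dependent applied current from the protocol.  This
#' is the reference implementation; [simulate()] uses an equivalent
#' compiled right-hand side and is cross-checked against this one in the
#' tests.
#'
#' @param model A [network_model()].
#' @param protocol A \code{"stim_protocol"} (or \code{NULL} for no
#'   stimulus).
#' @return List with \code{derivs(t, y)} and the [state_layout()].
#' @export
assemble_system <- function(model, protocol = NULL) {
  layout <- state_layout(model)
  ids <- names(model$neurons)
  derivs <- function(t, y) {
    if (length(y) != layout$dim) stop("state dimension mismatch",
                                      call. = FALSE)
    dy <- numeric(layout$dim)
    V <- vapply(ids, function(id) y[layout$neuron_offset[[id]] + 1L],
                numeric(1))
    # synaptic gates and per-neuron totals
    I_syn <- setNames(numeric(length(ids)), ids)
    for (k in seq_along(model$synapses)) {
      s <- model$synapses[[k]]
      sk <- y[layout$syn_offset[k] + 1L]
      Tc <- transmitter_concentration(V[[s$pre]], s)
      dy[layout$syn_offset[k] + 1L] <- synapse_gate_derivative(sk, Tc, s)
      I_syn[[s$post]] <- I_syn[[s$post]] + synaptic_current(sk, V[[s$post]], s)
    }
    for (id in ids) {
      n <- model$neurons[[id]]
      idx <- layout$neuron_offset[[id]] + seq_len(layout$neuron_dim[[id]])
      st <- setNames(y[idx], neuron_state_names(n$neuron_class))
      Iapp <- if (is.null(protocol)) 0 else applied_current(protocol, id, t)
      dy[idx] <- neuron_derivatives(st, n$params, I_syn[[id]], Iapp)
    }
    dy
  }
  list(derivs = derivs, layout = layout)
}

#' Connectivity table of a network
#'
#' @param model A [network_model()].
#' @return Data frame with columns pre, post, receptor, g, Vrev.
#' @export
connectivity_table <- function(model) {
  do.call(rbind, lapply(model$synapses, function(s) {
    data.frame(pre = s$pre, post = s$post, receptor = s$receptor,
               g = s$g, Vrev = s$Vrev, stringsAsFactors = FALSE)
  }))
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %d neurons, %d synapses\n",
              length(x$neurons), length(x$synapses)))
  cls <- vapply(x$neurons, `[[`, "", "neuron_class")
  cat("  neurons:", paste(sprintf("%s(%s)", names(x$neurons),
                                  ifelse(cls == "HVC_X", "E", "I")),
                          collapse = " "), "\n")
  cat("  stimulus targets:",
      paste(names(x$stimulus_targets),
            vapply(x$stimulus_targets, paste, "", collapse = "+"),
            sep = "=", collapse = "  "), "\n")
  invisible(x)
}
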