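# Numerical solution of the assembled network ODE system.
#
# The system is compiled once per run into a flat parameter vector consumed
# by the C right-hand side (src/csn_rhs.c).  Because the stimulus is a sum
# of DC pulses, the integration is split at pulse on/off times so the
# adaptive solvers never step across a discontinuity in the applied
# current.

PARMS_LEN <- 4096

# Pack model + protocol into the flat parameter vector for the compiled
# right-hand side.
network_parms <- function(model, protocol = NULL,
                          layout = state_layout(model)) {
  ids <- names(model$neurons)
  neu <- unlist(lapply(seq_along(ids), function(i) {
    n <- model$neurons[[i]]
    c(if (n$neuron_class == "HVC_X") 1 else 0,
      layout$neuron_offset[[i]],
      pack_neuron_params(n$params), 0)
  }))
  syn <- unlist(lapply(seq_along(model$synapses), function(k) {
    s <- model$synapses[[k]]
    c(match(s$pre, ids) - 1L, match(s$post, ids) - 1L,
      s$g, s$Vrev, s$ar, s$ad, s$Tmax, s$Kp, s$VT,
      layout$syn_offset[k])
  }))
  pul <- numeric(0)
  n_pul <- 0L
  if (!is.null(protocol) && nrow(protocol$pulses)) {
    pl <- protocol$pulses
    keep <- pl$target %in% ids
    pl <- pl[keep, , drop = FALSE]
    n_pul <- nrow(pl)
    pul <- unlist(lapply(seq_len(n_pul), function(k) {
      c(match(pl$target[k], ids) - 1L, pl$onset[k], pl$duration[k],
        pl$amplitude[k])
    }))
  }
  pv <- c(length(ids), length(model$synapses), n_pul, 0, neu, syn, pul)
  if (length(pv) > PARMS_LEN) stop("network too large for parameter block",
                                   call. = FALSE)
  c(pv, numeric(PARMS_LEN - length(pv)))
}

.solver_method <- function(method) {
  switch(method,
         lsoda = "lsoda",
         ode23 = deSolve::rkMethod("rk23bs"),
         ode45 = deSolve::rkMethod("rk45dp7"),
         bdf = "bdf",
         stop("unknown solver method: ", method, call. = FALSE))
}

# Default starting guess: every neuron at its class-typical subthreshold
# voltage with gates at steady state, synapses closed.
default_initial_state <- function(model, layout = state_layout(model)) {
  y <- numeric(layout$dim)
  for (id in names(model$neurons)) {
    n <- model$neurons[[id]]
    V0 <- if (n$neuron_class == "HVC_X") -70 else -65
    idx <- layout$neuron_offset[[id]] + seq_len(layout$neuron_dim[[id]])
    y[idx] <- initial_neuron_state(n$params, V0)
  }
  names(y) <- layout$state_names
  y
}

#' Resting state of a zero-stimulus network
#'
#' Relaxes the unstimulated system for \code{t_relax} ms from a
#' subthreshold initial guess, then refines the endpoint with a damped
#' Newton iteration on the reference derivative function so that every
#' component of the derivative is below \code{tol}.
#'
#' @param model A [network_model()].
#' @param t_relax Relaxation horizon (ms).
#' @param tol Maximum absolute derivative accepted at the returned state.
#' @param y0 Optional starting guess (defaults to a subthreshold state).
#' @param refine Run the Newton refinement (default TRUE).
#' @return Named state vector at rest.
#' @export
find_rest_state <- function(model, t_relax = 2000, tol = 1e-6, y0 = NULL,
                            refine = TRUE) {
  layout <- state_layout(model)
  if (is.null(y0)) y0 <- default_initial_state(model, layout)
  pv <- network_parms(model, NULL, layout)
  out <- deSolve::ode(y = y0, times = c(0, t_relax / 2, t_relax),
                      func = "csn_derivs", parms = pv,
                      dllname = "csnsim", initfunc = "csn_initmod",
                      method = "lsoda", rtol = 1e-10, atol = 1e-10)
  y <- out[nrow(out), -1]
  sys <- assemble_system(model, NULL)
  f <- function(v) sys$derivs(0, v)
  fy <- f(y)
  if (refine && max(abs(fy)) > tol) {
    for (iter in 1:25) {
      if (max(abs(fy)) <= tol / 10) break
      J <- numeric_jacobian(f, y, fy)
      step <- tryCatch(solve(J, -fy), error = function(e) NULL)
      if (is.null(step)) break
      lambda <- 1
      repeat {
        y_new <- y + lambda * step
        fy_new <- tryCatch(f(y_new), error = function(e) NULL)
        if (!is.null(fy_new) && all(is.finite(fy_new)) &&
            max(abs(fy_new)) < max(abs(fy))) {
          y <- y_new
          fy <- fy_new
          break
        }
        lambda <- lambda / 2
        if (lambda < 1e-6) break
      }
      if (lambda < 1e-6) break
    }
  }
  if (max(abs(fy)) > tol) {
    stop(sprintf(
      "rest state did not converge: max |dy/dt| = %.3g (component %s)",
      max(abs(fy)), layout$state_names[which.max(abs(fy))]),
      call. = FALSE)
  }
  names(y) <- layout$state_names
  y
}

numeric_jacobian <- function(f, y, fy = f(y), h = 1e-6) {
  n <- length(y)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    yp <- y
    hj <- h * max(1, abs(y[j]))
    yp[j] <- yp[j] + hj
    J[, j] <- (f(yp) - fy) / hj
  }
  J
}

#' Simulate a network under a stimulus protocol
#'
#' Adaptive-step integration of the compiled network system with output on
#' a uniform grid.  The run starts from the network's resting state (found
#' automatically unless supplied) at t = 0, i.e. 100 ms before the default
#' S1 onset, so event times are directly comparable across runs.
#'
#' @param model A [network_model()].
#' @param protocol A \code{"stim_protocol"} or \code{NULL}.
#' @param t_end End of the simulated window (ms); defaults to the last
#'   pulse offset plus 400 ms.
#' @param dt_out Uniform output step (ms).
#' @param method One of \code{"lsoda"} (default), \code{"ode23"}
#'   (Bogacki-Shampine 2(3)), \code{"ode45"} (Dormand-Prince 4(5)) or
#'   \code{"bdf"} (implicit fallback).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param rest Optional precomputed rest state (see [find_rest_state()]);
#'   passing it skips the rest-state search, which is the dominant cost for
#'   repeated runs of the same model.
#' @return Object of class \code{"sim_result"}: list with \code{time},
#'   \code{states} (matrix, one named column per state variable),
#'   \code{model}, \code{protocol}, \code{layout} and \code{solver}.
#' @export
simulate <- function(model, protocol = NULL, t_end = NULL, dt_out = 0.01,
                     method = "lsoda", rtol = 1e-6, atol = 1e-8,
                     rest = NULL) {
  layout <- state_layout(model)
  if (is.null(t_end)) {
    t_end <- if (is.null(protocol)) 500 else protocol_horizon(protocol)
  }
  if (is.null(rest)) rest <- find_rest_state(model)
  if (length(rest) != layout$dim) stop("rest state dimension mismatch",
                                       call. = FALSE)
  pv <- network_parms(model, protocol, layout)
  mth <- .solver_method(method)
  grid <- seq(0, t_end, by = dt_out)
  edges <- numeric(0)
  if (!is.null(protocol) && nrow(protocol$pulses)) {
    edges <- c(protocol$pulses$onset,
               protocol$pulses$onset + protocol$pulses$duration)
  }
  bounds <- sort(unique(c(0, t_end, edges[edges > 0 & edges < t_end])))
  y <- rest
  rows <- vector("list", length(bounds) - 1)
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]
    t1 <- bounds[i + 1]
    inner <- grid[grid > t0 + 1e-9 & grid < t1 - 1e-9]
    tseg <- c(t0, inner, t1)
    out <- deSolve::ode(y = y, times = tseg, func = "csn_derivs",
                        parms = pv, dllname = "csnsim",
                        initfunc = "csn_initmod", method = mth,
                        rtol = rtol, atol = atol, maxsteps = 500000)
    if (any(!is.finite(out))) {
      bad <- which(!is.finite(out), arr.ind = TRUE)[1, ]
      stop(sprintf(
        "solver produced a non-finite value at t = %.3f ms in component %s",
        out[bad[1], 1],
        c("time", layout$state_names)[bad[2]]), call. = FALSE)
    }
    y <- out[nrow(out), -1]
    on_grid <- abs(out[, 1] / dt_out - round(out[, 1] / dt_out)) < 1e-6
    if (i > 1) on_grid[1] <- FALSE  # boundary row already emitted
    rows[[i]] <- out[on_grid, , drop = FALSE]
  }
  full <- do.call(rbind, rows)
  states <- full[, -1, drop = FALSE]
  colnames(states) <- layout$state_names
  res <- list(time = full[, 1], states = states, model = model,
              protocol = protocol, layout = layout,
              solver = list(method = method, rtol = rtol, atol = atol,
                            dt_out = dt_out, t_end = t_end))
  class(res) <- "sim_result"
  res
}

#' Extract one neuron's voltage trace
#'
#' @param result A \code{"sim_result"}.
#' @param id Neuron label.
#' @return Numeric vector of V(t) on the result's time grid.
#' @export
voltage_trace <- function(result, id) {
  col <- paste0(id, ".V")
  if (!col %in% colnames(result$states)) {
    stop("no such neuron in result: ", id, call. = FALSE)
  }
  result$states[, col]
}

#' Extract one state variable's trajectory
#'
#' @param result A \code{"sim_result"}.
#' @param id Neuron label.
#' @param var State name (\code{"V"}, \code{"n"}, \code{"h"}, \code{"e"},
#'   \code{"rT"}, \code{"rf"}, \code{"rs"}, \code{"Ca"}).
#' @return Numeric vector of the trajectory.
#' @export
state_trace <- function(result, id, var) {
  col <- paste0(id, ".", var)
  if (!col %in% colnames(result$states)) {
    stop("no stored trajectory for ", col, call. = FALSE)
  }
  result$states[, col]
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf(
    "<sim_result> %d neurons, t in [0, %g] ms, dt_out = %g ms, method %s\n",
    length(x$model$neurons), max(x$time), x$solver$dt_out,
    x$solver$method))
  if (!is.null(x$protocol)) {
    cat(sprintf("  protocol: %s (delay %g ms)\n", x$protocol$condition,
                x$protocol$delay))
  }
  invisible(x)
}

#' Plot membrane-potential traces of a simulation
#'
#' @param x A \code{"sim_result"}.
#' @param ids Neuron labels to plot (default: all).
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.sim_result <- function(x, ids = names(x$model$neurons), ...) {
  V <- sapply(ids, function(id) voltage_trace(x, id))
  graphics::matplot(x$time, V, type = "l", lty = 1,
                    xlab = "time (ms)", ylab = "V (mV)", ...)
  graphics::legend("topright", legend = ids, col = seq_along(ids),
                   lty = 1, cex = 0.7, bty = "n")
  invisible(x)
}

#' Export a simulation as a wide data frame
#'
#' @param x A \code{"sim_result"}.
#' @param row.names,optional Unused (S3 signature).
#' @param ... Unused.
#' @return Data frame: time plus one column per state variable.
#' @export
as.data.frame.sim_result <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  data.frame(time = x$time, x$states, check.names = FALSE)
}
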