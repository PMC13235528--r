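# Spike detection, burst/combination classification and windowed
# quantification of the rebound-related intrinsic currents.

#' Detect spikes in a voltage trace
#'
#' Upward crossings of a fixed detection threshold, with a dead time so a
#' single action potential is never counted twice.
#'
#' @param V Voltage trace (mV) on a uniform time grid.
#' @param time Time grid (ms), same length as \code{V}.
#' @param threshold Detection threshold (mV).
#' @param dead_time Minimum separation between detected spikes (ms).
#' @return Numeric vector of spike times (ms), strictly increasing.
#' @export
detect_spikes <- function(V, time, threshold = -20, dead_time = 1) {
  stopifnot(length(V) == length(time))
  up <- which(V[-1] >= threshold & V[-length(V)] < threshold) + 1L
  if (!length(up)) return(numeric(0))
  times <- time[up]
  keep <- c(TRUE, diff(times) >= dead_time)
  # enforce the dead time sequentially (diff-based pruning can chain)
  out <- times[1]
  for (t in times[-1]) {
    if (t - out[length(out)] >= dead_time) out <- c(out, t)
  }
  out
}

#' Spike train of one neuron in a simulation
#'
#' @param result A \code{"sim_result"}.
#' @param id Neuron label.
#' @inheritParams detect_spikes
#' @return Object of class \code{"spike_train"}: list with \code{id} and
#'   \code{times}.
#' @export
spike_train <- function(result, id, threshold = -20, dead_time = 1) {
  st <- detect_spikes(voltage_trace(result, id), result$time,
                      threshold, dead_time)
  structure(list(id = id, times = st), class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s: %d spike(s)", x$id, length(x$times)))
  if (length(x$times)) {
    cat(sprintf(" in [%.2f, %.2f] ms", min(x$times), max(x$times)))
  }
  cat("\n")
  invisible(x)
}

#' Classify the CSN response as combination success or failure
#'
#' A response counts as a successful stimulus combination if the CSN fires
#' a burst of 4 to 12 spikes spanning at most 80 ms.  Spikes are counted
#' over the whole run (the CSN is silent outside the facilitated burst by
#' construction of the circuit).
#'
#' @param result A \code{"sim_result"} containing a neuron \code{"CSN"}.
#' @param threshold,dead_time Spike-detector settings.
#' @param min_spikes,max_spikes,max_span Burst acceptance band.
#' @return Object of class \code{"combination_outcome"}: list with
#'   \code{spike_count}, \code{burst_span} (ms), \code{success},
#'   \code{condition} and \code{spike_times}.
#' @export
classify_combination <- function(result, threshold = -20, dead_time = 1,
                                 min_spikes = 4, max_spikes = 12,
                                 max_span = 80) {
  st <- spike_train(result, "CSN", threshold, dead_time)
  n <- length(st$times)
  span <- if (n >= 2) max(st$times) - min(st$times) else 0
  structure(list(
    spike_count = n,
    burst_span = span,
    success = n >= min_spikes && n <= max_spikes && span <= max_span,
    condition = if (is.null(result$protocol)) "none"
                else result$protocol$condition,
    spike_times = st$times
  ), class = "combination_outcome")
}

#' @export
print.combination_outcome <- function(x, ...) {
  cat(sprintf(
    "<combination_outcome> condition '%s': %d spike(s), span %.1f ms -> %s\n",
    x$condition, x$spike_count, x$burst_span,
    if (x$success) "SUCCESS" else "failure"))
  invisible(x)
}

#' Reconstruct intrinsic currents along a stored trajectory
#'
#' Pointwise evaluation of the H-current and T-type calcium current
#' formulas on the stored voltage and gate trajectories of one neuron, in
#' the model's arbitrary units (raw formula output; negative deflections
#' are inward, depolarizing).
#'
#' @param result A \code{"sim_result"}.
#' @param id Neuron label (default the CSN).
#' @return Data frame with columns \code{time}, \code{IH}, \code{ICaT}.
#' @export
reconstruct_currents <- function(result, id = "CSN") {
  params <- result$model$neurons[[id]]$params
  if (is.null(params)) stop("no such neuron: ", id, call. = FALSE)
  V <- voltage_trace(result, id)
  IH <- h_current(V, state_trace(result, id, "rf"),
                  state_trace(result, id, "rs"), params)
  ICaT <- t_current(V, state_trace(result, id, "rT"), params)
  data.frame(time = result$time, IH = IH, ICaT = ICaT)
}

#' Windowed peak quantification of IH and ICaT across delays
#'
#' For each delay condition, the H-current is quantified over the
#' inter-stimulus gap window (from S1 offset to S2 onset) and the T-type
#' current over a 100 ms window starting at S2 onset; the peak absolute
#' value in each window is reported and, per current, normalized to its
#' maximum across the supplied delays.
#'
#' @param results Named list of \code{"sim_result"} objects, one per delay;
#'   each must carry a paired protocol (its \code{delay} field is used).
#' @param id Neuron label to quantify (default the CSN).
#' @param post_window Length of the post-S2-onset window for ICaT (ms).
#' @return Data frame with one row per delay: \code{delay},
#'   \code{peak_abs_IH}, \code{peak_abs_ICaT}, \code{norm_IH},
#'   \code{norm_ICaT}.
#' @export
quantify_current_windows <- function(results, id = "CSN",
                                     post_window = 100) {
  rows <- lapply(results, function(res) {
    pr <- res$protocol
    if (is.null(pr)) stop("result has no protocol", call. = FALSE)
    s1 <- pr$pulses[1, ]
    s1_off <- s1$onset + s1$duration
    s2_on <- s1_off + pr$delay
    if (s2_on + post_window > max(res$time)) {
      stop("quantification window extends beyond the simulated horizon",
           call. = FALSE)
    }
    cur <- reconstruct_currents(res, id)
    gap <- cur$time >= s1_off & cur$time <= s2_on
    post <- cur$time >= s2_on & cur$time <= s2_on + post_window
    data.frame(delay = pr$delay,
               peak_abs_IH = max(abs(cur$IH[gap])),
               peak_abs_ICaT = max(abs(cur$ICaT[post])))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$delay), ]
  out$norm_IH <- out$peak_abs_IH / max(out$peak_abs_IH)
  out$norm_ICaT <- out$peak_abs_ICaT / max(out$peak_abs_ICaT)
  rownames(out) <- NULL
  out
}

#' Hyperpolarization epochs of a voltage trace
#'
#' Maximal intervals in which the membrane potential stays more than
#' \code{margin} mV below the resting potential; used to delimit the
#' inhibition-driven integration window of the CSN.
#'
#' @param V Voltage trace (mV) on a uniform grid.
#' @param time Time grid (ms).
#' @param v_rest Resting potential (mV); taken from the first sample when
#'   missing.
#' @param margin Depth below rest required to count as hyperpolarized (mV).
#' @return Data frame with columns \code{start}, \code{end}, \code{min_V}
#'   (one row per epoch; zero rows if never hyperpolarized).
#' @export
hyperpolarization_epochs <- function(V, time, v_rest = NULL, margin = 2) {
  if (is.null(v_rest)) v_rest <- V[1]
  below <- V < v_rest - margin
  if (!any(below)) {
    return(data.frame(start = numeric(0), end = numeric(0),
                      min_V = numeric(0)))
  }
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  do.call(rbind, lapply(keep, function(k) {
    i <- starts[k]:ends[k]
    data.frame(start = time[i[1]], end = time[i[length(i)]],
               min_V = min(V[i]))
  }))
}

#' Minimum CSN membrane potential during the integration window
#'
#' Convenience wrapper: the deepest membrane potential reached by the CSN
#' in the hyperpolarization epoch(s) between S1 onset and S2 onset.
#'
#' @param result A \code{"sim_result"} of a paired-protocol run.
#' @param margin Epoch detection margin (mV).
#' @return Minimum V (mV) over the pre-S2 hyperpolarization; \code{NA} if
#'   the CSN is never hyperpolarized in that interval.
#' @export
integration_window_min <- function(result, margin = 2) {
  pr <- result$protocol
  s1 <- pr$pulses[1, ]
  s2_on <- s1$onset + s1$duration + pr$delay
  sel <- result$time >= s1$onset & result$time <= s2_on
  V <- voltage_trace(result, "CSN")
  ep <- hyperpolarization_epochs(V[sel], result$time[sel],
                                 v_rest = V[1], margin = margin)
  if (!nrow(ep)) return(NA_real_)
  min(ep$min_V)
}
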