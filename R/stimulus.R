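# DC-pulse stimulus protocols.
#
# A stimulus-selective input neuron is driven by a square current pulse for
# the duration of "its" stimulus.  Protocols are pure data: a table of
# pulses (target, onset, duration, amplitude) plus a condition label and
# the inter-stimulus delay, measured from S1 offset to S2 onset.  Pulse
# intervals are half-open [onset, onset + duration).

S1_ONSET_MS <- 100

new_protocol <- function(pulses, condition, delay) {
  stopifnot(is.data.frame(pulses))
  if (nrow(pulses) && any(pulses$duration <= 0)) {
    stop("pulse durations must be positive", call. = FALSE)
  }
  if (nrow(pulses) && any(pulses$onset < 0)) {
    stop("pulse onsets must be nonnegative", call. = FALSE)
  }
  structure(list(pulses = pulses, condition = condition, delay = delay),
            class = "stim_protocol")
}

#' Paired-stimulus protocol (S1 then S2)
#'
#' S1 is a DC pulse on the S1 target starting at t = 100 ms (the settling
#' period before stimulation); S2 starts \code{delay} ms after S1 offset.
#' A negative delay expresses the premature-arrival (overlap) condition in
#' which S2 begins before S1 ends.
#'
#' @param delay Gap from S1 offset to S2 onset (ms); may be negative down
#'   to \code{-dur1}.
#' @param dur1,dur2 Pulse durations (ms).
#' @param amp1,amp2 Pulse amplitudes (pA).
#' @param s1_target,s2_target Neuron ids receiving the pulses.
#' @return Object of class \code{"stim_protocol"}.
#' @examples
#' make_paired_protocol(150)$pulses  # S2 onset at 300 ms
#' @export
make_paired_protocol <- function(delay, dur1 = 50, dur2 = 50,
                                 amp1 = 200, amp2 = 200,
                                 s1_target = "A", s2_target = "B") {
  if (dur1 <= 0 || dur2 <= 0) {
    stop("pulse durations must be positive", call. = FALSE)
  }
  if (delay < -dur1) {
    stop("delay must be >= -dur1", call. = FALSE)
  }
  pulses <- data.frame(
    target = c(s1_target, s2_target),
    onset = c(S1_ONSET_MS, S1_ONSET_MS + dur1 + delay),
    duration = c(dur1, dur2),
    amplitude = c(amp1, amp2),
    stringsAsFactors = FALSE
  )
  cond <- if (delay < 0) "overlap" else "paired"
  new_protocol(pulses, cond, delay)
}

#' Control protocols: reversed order, single and repeated stimuli
#'
#' \describe{
#'   \item{reversed}{the S2 target is pulsed first, the S1 target second.}
#'   \item{S1_only / S2_only}{a single pulse on one target.}
#'   \item{S1_S1 / S2_S2}{two pulses on the same target, separated by
#'     \code{delay}.}
#' }
#'
#' @param condition One of \code{"reversed"}, \code{"S1_only"},
#'   \code{"S2_only"}, \code{"S1_S1"}, \code{"S2_S2"}.
#' @inheritParams make_paired_protocol
#' @param dur,amp Pulse duration (ms) and amplitude (pA), shared by both
#'   pulses.
#' @return Object of class \code{"stim_protocol"}.
#' @export
make_control_protocol <- function(condition = c("reversed", "S1_only",
                                                "S2_only", "S1_S1", "S2_S2"),
                                  delay = 0, dur = 50, amp = 200,
                                  s1_target = "A", s2_target = "B") {
  condition <- match.arg(condition)
  t0 <- S1_ONSET_MS
  t1 <- t0 + dur + delay
  pulses <- switch(condition,
    reversed = data.frame(target = c(s2_target, s1_target),
                          onset = c(t0, t1)),
    S1_only = data.frame(target = s1_target, onset = t0),
    S2_only = data.frame(target = s2_target, onset = t0),
    S1_S1 = data.frame(target = c(s1_target, s1_target),
                       onset = c(t0, t1)),
    S2_S2 = data.frame(target = c(s2_target, s2_target),
                       onset = c(t0, t1))
  )
  pulses$duration <- dur
  pulses$amplitude <- amp
  pulses$target <- as.character(pulses$target)
  new_protocol(pulses, condition, delay)
}

#' Applied current for one neuron at time t
#'
#' Sums the amplitudes of all pulses covering \code{t} for the given
#' neuron; pulse windows are half-open, so the current is 0 at exactly
#' \code{onset + duration}.
#'
#' @param protocol A \code{"stim_protocol"}.
#' @param neuron_id Neuron label.
#' @param t Time (ms). Vectorized.
#' @return Applied current (pA).
#' @export
applied_current <- function(protocol, neuron_id, t) {
  p <- protocol$pulses
  p <- p[p$target == neuron_id, , drop = FALSE]
  out <- numeric(length(t))
  for (i in seq_len(nrow(p))) {
    on <- t >= p$onset[i] & t < p$onset[i] + p$duration[i]
    out[on] <- out[on] + p$amplitude[i]
  }
  out
}

#' Total injected charge of a protocol
#'
#' Audit quantity: sum of amplitude x duration over all pulses (pA ms).
#'
#' @param protocol A \code{"stim_protocol"}.
#' @return Charge in pA*ms.
#' @export
protocol_charge <- function(protocol) {
  sum(protocol$pulses$amplitude * protocol$pulses$duration)
}

# Default simulation horizon: last pulse offset plus 400 ms of post-burst
# dynamics (or 500 ms for an empty protocol).
protocol_horizon <- function(protocol, tail = 400) {
  p <- protocol$pulses
  if (!nrow(p)) return(500)
  max(p$onset + p$duration) + tail
}

#' @export
print.stim_protocol <- function(x, ...) {
  cat(sprintf("<stim_protocol> condition '%s', delay %g ms, %d pulse(s)\n",
              x$condition, x$delay, nrow(x$pulses)))
  print(x$pulses, row.names = FALSE)
  invisible(x)
}
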