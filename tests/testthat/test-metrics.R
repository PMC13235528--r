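# Spike detection, burst classification, current reconstruction and
# windowed quantification.

fake_result <- function(V, time, condition = "paired", delay = 50) {
  structure(list(
    time = time,
    states = matrix(V, ncol = 1, dimnames = list(NULL, "CSN.V")),
    model = list(neurons = list(CSN = list(params = NULL))),
    protocol = list(condition = condition, delay = delay,
                    pulses = data.frame(target = "A", onset = 100,
                                        duration = 50, amplitude = 200))
  ), class = "sim_result")
}

bump_trace <- function(time, centers, width = 1, peak = 20,
                       base = -65) {
  V <- rep(base, length(time))
  for (ctr in centers) {
    V <- pmax(V, base + (peak - base) * exp(-((time - ctr) / width)^2))
  }
  V
}

test_that("spike detection counts threshold crossings with a dead time", {
  t <- seq(0, 100, by = 0.05)
  expect_length(detect_spikes(rep(-65, length(t)), t), 0)
  V <- bump_trace(t, c(20, 50, 80))
  expect_length(detect_spikes(V, t), 3)
  # two excursions closer than the dead time collapse into one
  V2 <- bump_trace(t, c(20, 20.5), width = 0.15)
  expect_length(detect_spikes(V2, t, dead_time = 1), 1)
  # threshold shift within reason does not change the count
  expect_length(detect_spikes(V, t, threshold = -30), 3)
  expect_length(detect_spikes(V, t, threshold = -10), 3)
})

test_that("combination classification applies the burst acceptance band", {
  t <- seq(0, 500, by = 0.05)
  ok <- classify_combination(fake_result(
    bump_trace(t, seq(300, 340, by = 8)), t))        # 6 spikes over 40 ms
  expect_true(ok$success)
  expect_equal(ok$spike_count, 6)
  expect_equal(ok$burst_span, 40, tolerance = 0.1)
  too_few <- classify_combination(fake_result(bump_trace(t, c(300, 320)),
                                              t))
  expect_false(too_few$success)
  too_many <- classify_combination(fake_result(
    bump_trace(t, seq(300, 336, by = 3)), t))        # 13 spikes
  expect_equal(too_many$spike_count, 13)
  expect_false(too_many$success)
  too_long <- classify_combination(fake_result(
    bump_trace(t, seq(300, 420, by = 30)), t))       # 5 spikes over 120 ms
  expect_false(too_long$success)
})

test_that("reconstructed currents equal the biophysics formulas applied to
          the stored states", {
  res <- sim_paired(50)
  cur <- reconstruct_currents(res, "CSN")
  p <- default_net()$neurons$CSN$params
  i <- seq(1, length(res$time), by = 500)
  ih <- h_current(voltage_trace(res, "CSN")[i],
                  state_trace(res, "CSN", "rf")[i],
                  state_trace(res, "CSN", "rs")[i], p)
  icat <- t_current(voltage_trace(res, "CSN")[i],
                    state_trace(res, "CSN", "rT")[i], p)
  expect_equal(cur$IH[i], ih)
  expect_equal(cur$ICaT[i], icat)
  # zero crossings at the defining conditions
  expect_equal(h_current(p$Vh, 0.5, 0.5, p), 0)
  expect_equal(t_current(-50, 0, p), 0)
})

test_that("hyperpolarization epochs delimit the integration window", {
  t <- seq(0, 400, by = 0.1)
  flat <- rep(-66, length(t))
  expect_equal(nrow(hyperpolarization_epochs(flat, t)), 0)
  V <- flat - ifelse(t >= 100 & t < 200, 20, 0)
  ep <- hyperpolarization_epochs(V, t, v_rest = -66)
  expect_equal(nrow(ep), 1)
  expect_equal(ep$start, 100, tolerance = 0.2)
  expect_equal(ep$end, 199.9, tolerance = 0.2)
  expect_equal(ep$min_V, -86)
  # on the real network the pre-S2 window tracks the delay
  e1 <- hyperpolarization_epochs(voltage_trace(sim_paired(50), "CSN"),
                                 sim_paired(50)$time)
  expect_gt(nrow(e1), 0)
})

test_that("windowed peaks are normalized per current and follow the delay
          dependence of priming", {
  results <- lapply(c(50, 150, 200, 280), sim_paired)
  q <- quantify_current_windows(results)
  expect_equal(q$delay, c(50, 150, 200, 280))
  expect_equal(max(q$norm_IH), 1)
  expect_equal(max(q$norm_ICaT), 1)
  expect_equal(q$norm_IH[q$delay == max(q$delay[which.max(q$norm_IH)])], 1)
  # H-current recruitment grows from 50 to 150 ms of delay
  expect_gte(q$peak_abs_IH[q$delay == 150], q$peak_abs_IH[q$delay == 50])
  # T-current availability collapses at 280 ms
  expect_lt(q$peak_abs_ICaT[q$delay == 280],
            q$peak_abs_ICaT[q$delay == 150])
  expect_error(quantify_current_windows(list(sim_paired(50)), post_window =
                                          1e5), "horizon")
})

test_that("epoch boundaries shift consistently as the delay grows", {
  r1 <- sim_paired(50)
  r2 <- sim_paired(70)
  last_ep <- function(res) {
    pr <- res$protocol
    s2 <- 150 + pr$delay
    sel <- res$time <= s2
    ep <- hyperpolarization_epochs(voltage_trace(res, "CSN")[sel],
                                   res$time[sel])
    ep$end[nrow(ep)]
  }
  expect_gt(last_ep(r2), last_ep(r1))
})
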