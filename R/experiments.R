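# Experiment drivers: delay sweep, two-parameter heatmaps, stimulus
# robustness sweeps, one-at-a-time (OAT) sensitivity analysis and the
# simple-motif battery.  Every cell of every grid is one deterministic
# simulation; results are independent of execution order.

new_sweep_grid <- function(axes, counts, success, context) {
  structure(list(axes = axes, counts = counts, success = success,
                 context = context), class = "sweep_grid")
}

#' @export
print.sweep_grid <- function(x, ...) {
  dims <- vapply(x$axes, function(a) length(a$values), integer(1))
  cat(sprintf("<sweep_grid> %s: %s cell(s)\n",
              paste(vapply(x$axes, `[[`, "", "name"), collapse = " x "),
              paste(dims, collapse = " x ")))
  print(x$counts)
  invisible(x)
}

#' Flatten a sweep grid to a long-format data frame
#'
#' @param x A \code{"sweep_grid"}.
#' @param row.names,optional,... Unused (S3 signature).
#' @return Data frame with one row per cell: axis values, \code{spikes},
#'   \code{success}.
#' @export
as.data.frame.sweep_grid <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  vals <- lapply(x$axes, `[[`, "values")
  names(vals) <- vapply(x$axes, `[[`, "", "name")
  out <- expand.grid(vals, KEEP.OUT.ATTRS = FALSE)
  out$spikes <- as.vector(x$counts)
  out$success <- as.vector(x$success)
  out
}

# Run one full-network simulation for a config + protocol and classify the
# CSN response.  The resting state is recomputed whenever the model itself
# changes; callers doing delay-only sweeps pass a cached rest state.
run_cell <- function(config, protocol, rest = NULL, net = NULL,
                     dt_out = 0.05) {
  if (is.null(net)) net <- build_full_network(config)
  if (is.null(rest)) rest <- find_rest_state(net)
  res <- simulate(net, protocol, dt_out = dt_out,
                  method = config$solver$method,
                  rtol = config$solver$rtol, atol = config$solver$atol,
                  rest = rest)
  classify_combination(res)
}

#' CSN spike count as a function of inter-stimulus delay
#'
#' Runs one paired-stimulus simulation per delay on the full network and
#' reports the CSN spike count and combination-success flag; the default
#' grid covers 0 to 300 ms in 20 ms steps (16 simulations).
#'
#' @param delays Delay values (ms).
#' @param config Network configuration.
#' @param dt_out Output grid step (ms) used for the sweep.
#' @return A \code{"sweep_grid"} with one \code{delay} axis.
#' @export
run_delay_sweep <- function(delays = seq(0, 300, by = 20),
                            config = default_network_config(),
                            dt_out = 0.05) {
  config <- validate_config(config)
  net <- build_full_network(config)
  rest <- find_rest_state(net)
  st <- config$stimulus
  out <- lapply(delays, function(d) {
    run_cell(config, make_paired_protocol(d, dur1 = st$duration,
                                          dur2 = st$duration,
                                          amp1 = st$amplitude,
                                          amp2 = st$amplitude),
             rest = rest, net = net, dt_out = dt_out)
  })
  new_sweep_grid(
    axes = list(list(name = "delay", values = delays, units = "ms")),
    counts = vapply(out, `[[`, integer(1), "spike_count"),
    success = vapply(out, `[[`, logical(1), "success"),
    context = list(kind = "delay_sweep", config_hash = config_hash(config))
  )
}

# Apply a sweep axis value to (config, delay) state.
apply_axis <- function(state, name, value) {
  if (name == "delay") state$delay <- value
  else if (name == "s1_duration") state$dur1 <- value
  else if (name == "s2_duration") state$dur2 <- value
  else if (name == "s1_amplitude") state$amp1 <- value
  else if (name == "s2_amplitude") state$amp2 <- value
  else state$config <- config_set(state$config, name, value)
  state
}

#' Two-parameter interaction heatmap of CSN spiking
#'
#' Sweeps two parameter axes on the full network and records the CSN spike
#' count per cell.  Axis names are either parameter paths understood by
#' [config_set()] (e.g. \code{"CSN.gCaT"}, \code{"CSN.gH"},
#' \code{"syn.I_A2->CSN"}, \code{"syn.B->CSN"}), the special name
#' \code{"delay"}, or stimulus fields (\code{"s1_duration"},
#' \code{"s2_duration"}, \code{"s1_amplitude"}, \code{"s2_amplitude"}).
#'
#' @param x_axis,y_axis Lists with \code{name} and \code{values} (and
#'   optionally \code{units}).
#' @param delay Inter-stimulus delay (ms) used when \code{"delay"} is not
#'   itself an axis.
#' @param config Network configuration.
#' @param dt_out Output grid step (ms).
#' @return A \code{"sweep_grid"} with a counts matrix (rows follow the x
#'   axis, columns the y axis).
#' @export
run_heatmap <- function(x_axis, y_axis, delay = 50,
                        config = default_network_config(),
                        dt_out = 0.05) {
  config <- validate_config(config)
  nx <- length(x_axis$values)
  ny <- length(y_axis$values)
  counts <- matrix(NA_integer_, nx, ny,
                   dimnames = list(x_axis$values, y_axis$values))
  success <- counts == 1
  st <- config$stimulus
  base <- list(config = config, delay = delay,
               dur1 = st$duration, dur2 = st$duration,
               amp1 = st$amplitude, amp2 = st$amplitude)
  for (j in seq_len(ny)) {
    for (i in seq_len(nx)) {
      state <- apply_axis(base, x_axis$name, x_axis$values[i])
      state <- apply_axis(state, y_axis$name, y_axis$values[j])
      pr <- make_paired_protocol(state$delay, dur1 = state$dur1,
                                 dur2 = state$dur2, amp1 = state$amp1,
                                 amp2 = state$amp2)
      o <- run_cell(state$config, pr, dt_out = dt_out)
      counts[i, j] <- o$spike_count
      success[i, j] <- o$success
    }
  }
  new_sweep_grid(
    axes = list(c(x_axis, list(role = "x")), c(y_axis, list(role = "y"))),
    counts = counts, success = success,
    context = list(kind = "heatmap", delay = delay,
                   config_hash = config_hash(config))
  )
}

#' Stimulus duration and intensity robustness sweeps
#'
#' Either a 2-D co-variation of the S1 and S2 stimulus parameter (duration
#' or intensity) or, with \code{marginals = TRUE}, the two 1-D sweeps in
#' which one stimulus is varied while the other stays at its default.
#' The inter-stimulus delay is fixed (50 ms by default).
#'
#' @param mode \code{"duration"} or \code{"intensity"}.
#' @param values Grid values; defaults to 10 equally spaced values over
#'   10-200 ms (duration) or 10-300 pA (intensity).
#' @param delay Inter-stimulus delay (ms).
#' @param marginals If TRUE return the two 1-D marginal sweeps instead of
#'   the full grid.
#' @param config Network configuration.
#' @param dt_out Output grid step (ms).
#' @return A \code{"sweep_grid"} (2-D), or a list of two \code{"sweep_grid"}
#'   objects (\code{s1}, \code{s2}) when \code{marginals = TRUE}.
#' @export
run_stimulus_sweeps <- function(mode = c("duration", "intensity"),
                                values = NULL, delay = 50,
                                marginals = FALSE,
                                config = default_network_config(),
                                dt_out = 0.05) {
  mode <- match.arg(mode)
  if (is.null(values)) {
    values <- if (mode == "duration") seq(10, 200, length.out = 10)
              else seq(10, 300, length.out = 10)
  }
  axis_names <- if (mode == "duration") {
    c("s1_duration", "s2_duration")
  } else {
    c("s1_amplitude", "s2_amplitude")
  }
  units <- if (mode == "duration") "ms" else "pA"
  if (marginals) {
    one <- function(nm) {
      grid <- run_heatmap(list(name = nm, values = values, units = units),
                          list(name = "delay", values = delay,
                               units = "ms"),
                          delay = delay, config = config, dt_out = dt_out)
      grid$axes <- grid$axes[1]
      grid$counts <- drop(grid$counts)
      grid$success <- drop(grid$success)
      grid$context$kind <- paste0("stimulus_marginal_", mode)
      grid
    }
    return(list(s1 = one(axis_names[1]), s2 = one(axis_names[2])))
  }
  grid <- run_heatmap(list(name = axis_names[1], values = values,
                           units = units),
                      list(name = axis_names[2], values = values,
                           units = units),
                      delay = delay, config = config, dt_out = dt_out)
  grid$context$kind <- paste0("stimulus_sweep_", mode)
  grid
}

#' Default success predicate for sensitivity analysis
#'
#' A configuration passes if (1) the default paired protocol at the given
#' delay produces a successful combination burst and (2) the reversed-order
#' and S2-only controls fail the burst criterion.
#'
#' @param delay Paired-protocol delay (ms).
#' @param dt_out Output grid step (ms).
#' @return Function of a configuration returning TRUE/FALSE.
#' @export
combination_predicate <- function(delay = 50, dt_out = 0.05) {
  function(config) {
    net <- build_full_network(config)
    rest <- tryCatch(find_rest_state(net), error = function(e) NULL)
    if (is.null(rest)) return(FALSE)
    ok <- tryCatch({
      paired <- run_cell(config, make_paired_protocol(delay), rest, net,
                         dt_out)
      if (!paired$success) return(FALSE)
      for (cond in c("reversed", "S2_only")) {
        ctl <- run_cell(config,
                        make_control_protocol(cond, delay = 0), rest, net,
                        dt_out)
        if (ctl$success) return(FALSE)
      }
      TRUE
    }, error = function(e) FALSE)
    ok
  }
}

#' One-at-a-time sensitivity range search
#'
#' Starting from the baseline value of one parameter, steps outward
#' multiplicatively (factor 1.25 by default) in each direction until the
#' success predicate fails, then refines the boundary by bisection.  All
#' other parameters stay at their configured values.
#'
#' @param parameter Parameter path as in [config_set()].
#' @param config Network configuration (must pass the predicate at
#'   baseline).
#' @param predicate Function of a configuration returning TRUE/FALSE;
#'   defaults to [combination_predicate()].
#' @param factor Multiplicative step.
#' @param max_steps Maximum outward steps per direction.
#' @param refine_rel Relative width at which bisection stops (boundaries
#'   are reported to roughly two significant figures by default).
#' @return Object of class \code{"oat_range"}: list with \code{parameter},
#'   \code{baseline}, \code{min}, \code{max} and \code{evaluations}.
#' @export
run_oat_search <- function(parameter, config = default_network_config(),
                           predicate = combination_predicate(),
                           factor = 1.25, max_steps = 12,
                           refine_rel = 0.05) {
  config <- validate_config(config)
  baseline <- get_parameter(config, parameter)
  n_eval <- 0L
  test <- function(v) {
    n_eval <<- n_eval + 1L
    predicate(config_set(config, parameter, v))
  }
  if (!test(baseline)) {
    stop("baseline configuration fails the predicate; OAT search is ",
         "ill-posed", call. = FALSE)
  }
  bound <- function(direction) {
    good <- baseline
    bad <- NULL
    for (k in seq_len(max_steps)) {
      cand <- good * factor^direction
      if (test(cand)) good <- cand else { bad <- cand; break }
    }
    if (is.null(bad)) return(good)  # no failure found within the budget
    while (abs(bad - good) > refine_rel * abs(good)) {
      mid <- (good + bad) / 2
      if (test(mid)) good <- mid else bad <- mid
    }
    good
  }
  upper <- bound(+1)
  lower <- bound(-1)
  structure(list(parameter = parameter, baseline = baseline,
                 min = lower, max = upper, evaluations = n_eval),
            class = "oat_range")
}

get_parameter <- function(config, path) {
  if (startsWith(path, "syn.")) {
    key <- substring(path, 5)
    v <- config$synapses[[key]]
    if (is.null(v)) stop("unknown synapse path: ", path, call. = FALSE)
    return(v)
  }
  parts <- strsplit(path, ".", fixed = TRUE)[[1]]
  v <- config$neurons[[parts[1]]][[parts[2]]]
  if (is.null(v)) {
    tmpl <- .neuron_templates()[[
      if (parts[1] %in% c("I1", "I2", "I_A1", "I_A2", "I_A3", "I_B"))
        "HVC_INT" else "HVC_X"]]
    v <- tmpl[[parts[2]]]
  }
  if (is.null(v)) stop("unknown parameter path: ", path, call. = FALSE)
  v
}

#' @export
print.oat_range <- function(x, ...) {
  cat(sprintf(
    "<oat_range> %s: baseline %g, accepted [%.3g, %.3g] (%d evaluations)\n",
    x$parameter, x$baseline, x$min, x$max, x$evaluations))
  invisible(x)
}

#' Outcome battery over the three simple motifs
#'
#' Runs each simple motif under the paired (0 ms), delayed (50 ms),
#' premature-overlap (S2 onset 30 ms before S1 offset) and reversed-order
#' conditions and tabulates the CSN outcome.
#'
#' @param kinds Motif kinds to include.
#' @param config Network configuration (its \code{motifs} block is used).
#' @param dt_out Output grid step (ms).
#' @return Data frame: motif, condition, spikes, success.
#' @export
run_motif_battery <- function(kinds = c("dual_excitatory",
                                        "dual_inhibitory",
                                        "inhibitory_excitatory"),
                              config = default_network_config(),
                              dt_out = 0.05) {
  config <- validate_config(config)
  rows <- list()
  for (kind in kinds) {
    net <- build_simple_motif(kind, config)
    rest <- find_rest_state(net)
    protocols <- list(
      paired = make_paired_protocol(0),
      delayed_50 = make_paired_protocol(50),
      overlap = make_paired_protocol(-30),
      reversed = make_control_protocol("reversed", delay = 0)
    )
    for (cond in names(protocols)) {
      res <- simulate(net, protocols[[cond]], dt_out = dt_out, rest = rest)
      o <- classify_combination(res)
      rows[[length(rows) + 1L]] <- data.frame(
        motif = kind, condition = cond, spikes = o$spike_count,
        success = o$success, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Plot a sweep grid
#'
#' 1-D sweeps are drawn as a spike-count line; 2-D sweeps as an image with
#' the x axis along rows.
#'
#' @param x A \code{"sweep_grid"}.
#' @param ... Passed to the underlying plot function.
#' @export
plot.sweep_grid <- function(x, ...) {
  if (length(x$axes) == 1 || is.null(dim(x$counts))) {
    graphics::plot(x$axes[[1]]$values, x$counts, type = "b", pch = 19,
                   xlab = paste0(x$axes[[1]]$name, " (",
                                 x$axes[[1]]$units %||% "", ")"),
                   ylab = "CSN spikes", ...)
  } else {
    graphics::image(x$axes[[1]]$values, x$axes[[2]]$values, x$counts,
                    xlab = x$axes[[1]]$name, ylab = x$axes[[2]]$name,
                    col = grDevices::hcl.colors(13, "viridis"), ...)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write sweep results and a run manifest to a directory
#'
#' Emits \code{results.csv} (long format) and \code{manifest.json} (axes,
#' context, solver settings, configuration hash) so any figure-analog
#' output can be regenerated from its manifest.
#'
#' @param grid A \code{"sweep_grid"} or the data frame from
#'   [run_motif_battery()].
#' @param dir Output directory (created if missing).
#' @param config The configuration used (stored in the manifest).
#' @return \code{dir}, invisibly.
#' @export
write_sweep <- function(grid, dir, config = default_network_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- if (is.data.frame(grid)) grid else as.data.frame(grid)
  utils::write.csv(df, file.path(dir, "results.csv"), row.names = FALSE)
  manifest <- list(
    context = if (is.data.frame(grid)) list(kind = "motif_battery")
              else grid$context,
    axes = if (is.data.frame(grid)) NULL else grid$axes,
    solver = config$solver,
    config_hash = config_hash(config)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' Run an experiment described by a configuration
#'
#' Thin driver used by the command-line interface: executes one named
#' experiment with the given configuration and writes its artifacts
#' (results table plus manifest) to \code{out_dir}.
#'
#' @param config Network configuration (validated; defaults filled).
#' @param experiment One of \code{"delay-sweep"}, \code{"heatmap"},
#'   \code{"stimulus-sweep"}, \code{"oat"}, \code{"motif-battery"}.
#' @param out_dir Output directory.
#' @param ... Passed to the experiment driver (e.g. \code{x_axis},
#'   \code{y_axis} for \code{"heatmap"}; \code{parameter} for
#'   \code{"oat"}).
#' @return The experiment result object, invisibly.
#' @export
run_from_config <- function(config, experiment, out_dir, ...) {
  config <- validate_config(config)
  result <- switch(experiment,
    "delay-sweep" = run_delay_sweep(config = config, ...),
    "heatmap" = run_heatmap(config = config, ...),
    "stimulus-sweep" = run_stimulus_sweeps(config = config, ...),
    "oat" = run_oat_search(config = config, ...),
    "motif-battery" = run_motif_battery(config = config, ...),
    stop("unknown experiment: ", experiment, call. = FALSE)
  )
  if (inherits(result, "oat_range")) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(result),
                         file.path(out_dir, "oat_range.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  } else {
    write_sweep(result, out_dir, config)
  }
  invisible(result)
}
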