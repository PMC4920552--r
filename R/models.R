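## Neuron models: coincidence counter and pure integrator.

pool_trains <- function(trains) {
  for (tr in trains)
    if (length(tr) > 1 && any(diff(tr) <= 0))
      stop("spike times must be strictly increasing (sorted) per fiber")
  x <- sort(unlist(trains, use.names = FALSE))
  if (is.null(x)) numeric(0) else x
}

new_output_train <- function(times, duration, params, n_candidates = NA,
                             seed = NULL) {
  structure(list(spike_times = times, duration = duration,
                 params_used = params, n_candidate_coincidences = n_candidates,
                 seed = seed),
            class = "output_spike_train")
}

#' @export
print.output_spike_train <- function(x, ...) {
  cat("Output spike train:", length(x$spike_times), "spikes in",
      x$duration, "s (", round(length(x$spike_times) / x$duration, 2),
      "spikes/s )\n")
  if (!is.na(x$n_candidate_coincidences))
    cat("  candidate coincidences before refractory rejection:",
        x$n_candidate_coincidences, "\n")
  invisible(x)
}

#' Mean output spike rate
#'
#' @param x An \code{output_spike_train}.
#' @return Spikes per second.
#' @export
output_rate <- function(x) {
  stopifnot(inherits(x, "output_spike_train"))
  length(x$spike_times) / x$duration
}

#' Effective threshold trace under inhibition
#'
#' Per-bin effective coincidence threshold: \code{theta} plus \code{delta}
#' for every inhibitory spike (pooled over fibers) in the trailing window
#' \code{(t - Delta, t]}. Elevations from overlapping inhibitory spikes add.
#'
#' This materializes one value per time bin; for long trials at fine dt use
#' \code{\link{mean_threshold_elevation}} for the time average instead.
#'
#' @param inh_trains List of inhibitory spike-time vectors (seconds), or a
#'   single numeric vector.
#' @param params A \code{\link{coincidence_params}}.
#' @param duration Duration in seconds.
#' @param dt Time step in seconds.
#' @return Numeric vector of length \code{round(duration/dt)}: the effective
#'   threshold at bin times \code{0, dt, 2 dt, ...}.
#' @examples
#' tr <- effective_threshold_trace(list(0.010), coincidence_params(),
#'                                 duration = 0.02, dt = 1e-4)
#' range(tr)  # 8 and 10
#' @export
effective_threshold_trace <- function(inh_trains, params, duration, dt) {
  stopifnot(inherits(params, "coincidence_params"), duration > 0, dt > 0)
  spikes <- if (is.list(inh_trains)) pool_trains(inh_trains)
            else sort(inh_trains)
  n_bins <- round(duration / dt)
  d_bins <- round(params$Delta / dt)
  elev <- numeric(n_bins)
  if (length(spikes)) {
    b <- round(spikes / dt)
    if (any(b < 0 | b >= n_bins)) stop("spike time outside [0, duration)")
    ## a spike at bin s elevates bins s .. s + d_bins - 1:
    ## difference array with +1 at s and -1 at s + d_bins (if inside trace)
    up <- tabulate(b + 1L, nbins = n_bins)
    dn_at <- b + d_bins
    dn <- tabulate(dn_at[dn_at <= n_bins - 1L] + 1L, nbins = n_bins)
    elev <- cumsum(up - dn)
  }
  params$theta + params$delta * elev
}

#' Time-averaged inhibitory threshold elevation
#'
#' The time average of the inhibition-induced threshold elevation over a
#' trial, computed exactly from the spike times (each inhibitory spike
#' elevates the threshold by \code{delta} over \code{Delta}, truncated at
#' the end of the trial). Equals the mean of
#' \code{effective_threshold_trace() - theta} up to grid rounding.
#'
#' With \code{n} fibers at rate \code{r}, the expectation is
#' \code{n * r * Delta * delta}: 0.768 inputs for 8 fibers at 30 spikes/s
#' with Delta = 1.6 ms and delta = 2.
#'
#' @inheritParams effective_threshold_trace
#' @return Mean elevation in input units.
#' @export
mean_threshold_elevation <- function(inh_trains, params, duration) {
  stopifnot(inherits(params, "coincidence_params"), duration > 0)
  spikes <- if (is.list(inh_trains)) pool_trains(inh_trains)
            else sort(inh_trains)
  if (!length(spikes)) return(0)
  covered <- pmin(spikes + params$Delta, duration) - spikes
  params$delta * sum(covered) / duration
}

#' Run the coincidence-counting neuron
#'
#' Slides a trailing coincidence window of width \code{W} along the time
#' grid; whenever the number of pooled excitatory input spikes in
#' \code{(t - W, t]} reaches or exceeds the effective threshold (theta plus
#' inhibitory elevation, see \code{\link{effective_threshold_trace}}), and at
#' least \code{T} has elapsed since the previous output spike, an output
#' spike is emitted at \code{t}. Super-threshold candidates inside the
#' refractory period are discarded (only the first spike is counted).
#'
#' The implementation is event-driven and exactly equivalent to the naive
#' per-bin simulation for every \code{dt} that resolves the input spike
#' times; halving \code{dt} leaves the output spike set unchanged.
#'
#' @param spikes A \code{spike_train_set} (see \code{\link{generate_input_set}}),
#'   or a list with elements \code{exc_trains}, \code{inh_trains},
#'   \code{duration} (and optionally \code{dt}).
#' @param params A \code{\link{coincidence_params}}.
#' @param dt Time step in seconds; defaults to the spike set's \code{dt},
#'   or 2e-6.
#' @return An object of class \code{"output_spike_train"} with elements
#'   \code{spike_times}, \code{duration}, \code{params_used} and
#'   \code{n_candidate_coincidences} (threshold crossings before refractory
#'   rejection).
#' @examples
#' sts <- generate_input_set(stimulus_spec(f_m = 300, duration = 1),
#'                           fiber_population(), "monaural", seed = 1)
#' run_coincidence_counter(sts, coincidence_params())
#' @export
run_coincidence_counter <- function(spikes, params, dt = NULL) {
  stopifnot(inherits(params, "coincidence_params"))
  if (is.null(dt)) dt <- if (!is.null(spikes$dt)) spikes$dt else 2e-6
  exc <- pool_trains(spikes$exc_trains)
  inh <- pool_trains(spikes$inh_trains)
  res <- .cc_counter(exc, inh, spikes$duration, dt, params$theta, params$W,
                     params$T, params$Delta, params$delta)
  new_output_train(res$spike_times, spikes$duration, params,
                   n_candidates = res$n_candidates,
                   seed = spikes$seed)
}

#' Run the pure-integrator neuron
#'
#' Timing-free control model: excitatory and inhibitory inputs received since
#' the end of the last refractory period are counted irrespective of their
#' arrival times, and an output spike is emitted at the first input event at
#' which \code{N_e - delta * N_i >= theta}. Counters then reset and inputs
#' arriving during the refractory period \code{T} are discarded. The running
#' difference may go negative (excess inhibition); it is not floored.
#'
#' @param spikes A \code{spike_train_set} or compatible list.
#' @param params An \code{\link{integrator_params}}.
#' @return An \code{"output_spike_train"} (candidate count is \code{NA}:
#'   the integrator has no window coincidences).
#' @examples
#' sts <- generate_input_set(stimulus_spec(f_m = 300, duration = 1),
#'                           fiber_population(), "monaural", seed = 1)
#' run_pure_integrator(sts, integrator_params())
#' @export
run_pure_integrator <- function(spikes, params) {
  stopifnot(inherits(params, "integrator_params"))
  exc <- pool_trains(spikes$exc_trains)
  inh <- pool_trains(spikes$inh_trains)
  res <- .pure_integrator(exc, inh, spikes$duration, params$theta,
                          params$T, params$delta)
  new_output_train(res$spike_times, spikes$duration, params,
                   n_candidates = NA, seed = spikes$seed)
}

#' Simulate one full trial
#'
#' Generates the input spike trains for a stimulus and runs the neuron model
#' selected by the class of \code{params} (coincidence counter or pure
#' integrator).
#'
#' @param stim A \code{\link{stimulus_spec}}.
#' @param pop A \code{\link{fiber_population}}.
#' @param params \code{\link{coincidence_params}} or
#'   \code{\link{integrator_params}}.
#' @param mode Input mode, see \code{\link{generate_input_set}}.
#' @param seed Integer master seed for the trial.
#' @param ... Passed to \code{\link{generate_input_set}} (e.g.
#'   \code{spont_inh}, \code{rate_fun}, \code{vs_fun}).
#' @return An \code{"output_spike_train"}.
#' @examples
#' run_trial(stimulus_spec(f_m = 300, duration = 2), fiber_population(),
#'           coincidence_params(), "monaural", seed = 7)
#' @export
run_trial <- function(stim, pop, params, mode = "monaural", seed, ...) {
  sts <- generate_input_set(stim, pop, mode, seed, ...)
  if (inherits(params, "coincidence_params"))
    run_coincidence_counter(sts, params)
  else if (inherits(params, "integrator_params"))
    run_pure_integrator(sts, params)
  else stop("'params' must be coincidence_params or integrator_params")
}
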