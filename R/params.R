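#' Stimulus specification
#'
#' Describes one driving condition: the envelope modulation frequency of an
#' amplitude-modulated (AM) sound, optional sound pressure levels at the two
#' ears, the phase difference between the inhibitory and excitatory input
#' streams, and the simulated duration and time step.
#'
#' @param f_m Modulation frequency in Hz (>= 0; 0 means an unmodulated
#'   stimulus).
#' @param level_ipsi,level_contra Sound pressure levels in dB at the
#'   ipsilateral (excitation-driving) and contralateral (inhibition-driving)
#'   ear. Only used in \code{"level_driven"} mode; may be \code{NULL}
#'   otherwise.
#' @param phase_diff Phase difference in degrees between inhibitory and
#'   excitatory input modulation. Positive values mean inhibition precedes
#'   excitation. Required for \code{"binaural"} mode.
#' @param duration Simulated time in seconds (> 0).
#' @param dt Simulation time step in seconds. The default of 2e-6 (2 us) is
#'   small enough that results do not depend on it; any smaller value gives
#'   statistically indistinguishable output.
#'
#' @return An object of class \code{"stimulus_spec"}.
#' @examples
#' stimulus_spec(f_m = 300, duration = 10)
#' @export
stimulus_spec <- function(f_m = 0, level_ipsi = NULL, level_contra = NULL,
                          phase_diff = NULL, duration = 100, dt = 2e-6) {
  stopifnot(is.numeric(f_m), length(f_m) == 1L, f_m >= 0,
            is.numeric(duration), length(duration) == 1L, duration > 0,
            is.numeric(dt), length(dt) == 1L, dt > 0)
  if (!is.null(phase_diff))
    stopifnot(is.numeric(phase_diff), length(phase_diff) == 1L)
  structure(list(f_m = f_m, level_ipsi = level_ipsi,
                 level_contra = level_contra, phase_diff = phase_diff,
                 duration = duration, dt = dt),
            class = "stimulus_spec")
}

#' Input fiber population
#'
#' Sizes and baseline parameters of the excitatory (ventral cochlear nucleus
#' bushy cell) and inhibitory (medial nucleus of the trapezoid body) fiber
#' populations converging on one model LSO neuron.
#'
#' @param n_exc Number of excitatory input fibers (default 20).
#' @param n_inh Number of inhibitory input fibers (default 8).
#' @param lambda0 Excitatory fiber intensity at zero modulation frequency, in
#'   spikes/s (default 180). May be a vector of length \code{n_exc} to give
#'   each fiber its own intensity (heterogeneous-input simulations).
#' @param lambda_inh_spont Spontaneous inhibitory fiber rate in spikes/s
#'   (default 30).
#' @param vs_max Maximum vector strength of phase-locked inputs, in [0, 1)
#'   (default 0.65).
#'
#' @return An object of class \code{"fiber_population"}.
#' @examples
#' fiber_population()
#' @export
fiber_population <- function(n_exc = 20, n_inh = 8, lambda0 = 180,
                             lambda_inh_spont = 30, vs_max = 0.65) {
  stopifnot(n_exc >= 0, n_inh >= 0, all(lambda0 >= 0),
            lambda_inh_spont >= 0, vs_max >= 0, vs_max < 1)
  if (length(lambda0) != 1L && length(lambda0) != n_exc)
    stop("'lambda0' must have length 1 or n_exc")
  structure(list(n_exc = as.integer(n_exc), n_inh = as.integer(n_inh),
                 lambda0 = lambda0, lambda_inh_spont = lambda_inh_spont,
                 vs_max = vs_max),
            class = "fiber_population")
}

#' Coincidence-counting neuron parameters
#'
#' The five parameters of the coincidence-counting LSO model: an output spike
#' is generated whenever the number of pooled excitatory input spikes inside
#' the trailing coincidence window \code{W} reaches the threshold, and each
#' inhibitory input spike transiently raises the threshold by \code{delta}
#' for a duration \code{Delta}. Output spikes closer than the refractory
#' period \code{T} to the previous accepted spike are discarded.
#'
#' All times are in seconds. Defaults are the standard parameter set:
#' theta = 8 inputs, W = 0.8 ms, T = 1.6 ms, Delta = 1.6 ms, delta = 2.
#'
#' @param theta Coincidence threshold in inputs (integer >= 1).
#' @param W Coincidence window width in seconds.
#' @param T Refractory period in seconds.
#' @param Delta Inhibition window in seconds.
#' @param delta Threshold increase per inhibitory spike (>= 0).
#'
#' @return An object of class \code{c("coincidence_params", "neuron_params")}.
#' @examples
#' coincidence_params()                 # defaults
#' coincidence_params(theta = 10)      # higher threshold
#' @export
coincidence_params <- function(theta = 8, W = 0.8e-3, T = 1.6e-3,
                               Delta = 1.6e-3, delta = 2) {
  stopifnot(theta >= 1, theta == round(theta), W > 0, T > 0, Delta > 0,
            delta >= 0)
  structure(list(theta = as.integer(theta), W = W, T = T,
                 Delta = Delta, delta = delta),
            class = c("coincidence_params", "neuron_params"))
}

#' Pure-integrator neuron parameters
#'
#' The timing-free control model: excitatory and inhibitory input spikes are
#' counted since the end of the last refractory period, irrespective of their
#' timing, and an output spike is generated when
#' \code{N_e - delta * N_i >= theta}.
#'
#' @param theta Threshold in inputs (integer >= 1).
#' @param T Refractory period in seconds.
#' @param delta Weight of one inhibitory input, in excitatory-input units.
#'
#' @return An object of class \code{c("integrator_params", "neuron_params")}.
#' @examples
#' integrator_params()
#' @export
integrator_params <- function(theta = 8, T = 1.6e-3, delta = 2) {
  stopifnot(theta >= 1, theta == round(theta), T > 0, delta >= 0)
  structure(list(theta = as.integer(theta), T = T, delta = delta),
            class = c("integrator_params", "neuron_params"))
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("AM stimulus: f_m =", x$f_m, "Hz, duration =", x$duration,
      "s, dt =", x$dt * 1e6, "us\n")
  if (!is.null(x$level_ipsi) || !is.null(x$level_contra))
    cat("  levels (ipsi/contra):", x$level_ipsi, "/", x$level_contra, "dB\n")
  if (!is.null(x$phase_diff))
    cat("  inhibition leads excitation by", x$phase_diff, "deg\n")
  invisible(x)
}

#' @export
print.fiber_population <- function(x, ...) {
  cat("Fiber population:", x$n_exc, "excitatory +", x$n_inh,
      "inhibitory fibers\n")
  cat("  lambda0 =", paste(signif(x$lambda0, 4), collapse = ", "),
      "spikes/s; spontaneous inhibition =", x$lambda_inh_spont,
      "spikes/s; max VS =", x$vs_max, "\n")
  invisible(x)
}

#' @export
print.coincidence_params <- function(x, ...) {
  cat("Coincidence-counting neuron: theta =", x$theta,
      "inputs, W =", x$W * 1e3, "ms, T =", x$T * 1e3,
      "ms, Delta =", x$Delta * 1e3, "ms, delta =", x$delta, "\n")
  invisible(x)
}

#' @export
print.integrator_params <- function(x, ...) {
  cat("Pure-integrator neuron: theta =", x$theta, "inputs, T =",
      x$T * 1e3, "ms, delta =", x$delta, "\n")
  invisible(x)
}
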