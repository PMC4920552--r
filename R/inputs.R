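## Input spike train generation: homogeneous and periodically modulated
## Poisson processes with von Mises cycle histograms.

#' Concentration parameter for a target vector strength
#'
#' Inverts the Bessel-function ratio VS = I1(k)/I0(k) of the von Mises
#' distribution: returns the concentration parameter k whose cycle histogram
#' has the requested vector strength.
#'
#' @param vs Target vector strength, in [0, 1).
#' @return Concentration parameter k >= 0 such that
#'   \code{besselI(k, 1) / besselI(k, 0)} equals \code{vs} to within 1e-8.
#'   Strictly increasing in \code{vs}.
#' @examples
#' vs_to_kappa(0)       # 0: uniform phase distribution
#' vs_to_kappa(0.65)
#' @export
vs_to_kappa <- function(vs) {
  if (!is.numeric(vs) || any(vs < 0) || any(vs >= 1))
    stop("'vs' must lie in [0, 1)")
  vapply(vs, function(v) {
    if (v == 0) return(0)
    ## I1/I0 is strictly increasing in k; bracket then bisect via uniroot.
    ## besselI overflows for very large k, so use exponentially scaled ratios.
    f <- function(k) besselI(k, 1, expon.scaled = TRUE) /
      besselI(k, 0, expon.scaled = TRUE) - v
    hi <- 1
    while (f(hi) < 0) hi <- hi * 2
    stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  }, numeric(1))
}

#' Modulation-frequency dependence of input fiber rate
#'
#' Mean discharge rate of a phase-locked input fiber as a linear, mildly
#' decreasing function of modulation frequency:
#' \code{lambda0 - 0.03 * f_m} spikes/s, floored at 0.
#'
#' @param f_m Modulation frequency in Hz (>= 0).
#' @param lambda0 Intensity at zero modulation frequency, spikes/s.
#' @return Mean fiber rate in spikes/s.
#' @examples
#' rate_vs_fm(300)   # 171
#' @export
rate_vs_fm <- function(f_m, lambda0 = 180) {
  stopifnot(all(f_m >= 0))
  pmax(lambda0 - 0.03 * f_m, 0)
}

#' Modulation-frequency dependence of input phase-locking
#'
#' Vector strength of a phase-locked input fiber as a monotonically
#' decreasing sigmoid of modulation frequency,
#' \code{vs_max * (1 - exp((f_m - 2000)/500)) / (1 + exp((f_m - 2000)/500))},
#' equivalently \code{vs_max * tanh((2000 - f_m)/1000)}, reaching zero at
#' f_m = 2000 Hz and clamped to 0 above it.
#'
#' @param f_m Modulation frequency in Hz (>= 0).
#' @param vs_max Maximum vector strength (default 0.65).
#' @return Vector strength in [0, vs_max).
#' @examples
#' vs_vs_fm(300)
#' vs_vs_fm(2000)  # 0
#' @export
vs_vs_fm <- function(f_m, vs_max = 0.65) {
  stopifnot(all(f_m >= 0))
  pmax(vs_max * tanh((2000 - f_m) / 1000), 0)
}

#' Level dependence of input fiber rate
#'
#' Sigmoidal rate-level function shared by excitatory and inhibitory input
#' fibers: \code{30 + 240 / (1 + exp(-(l - 20)/6))} spikes/s.
#'
#' @param l Sound pressure level in dB.
#' @return Mean fiber rate in spikes/s, in [30, 270).
#' @examples
#' rate_vs_level(20)  # 150
#' @export
rate_vs_level <- function(l) {
  30 + 240 / (1 + exp(-(l - 20) / 6.0))
}

#' Level dependence of input phase-locking
#'
#' Non-monotonic vector-strength-versus-level function, the product of a
#' rising sigmoid at low levels and a falling sigmoid at high levels:
#' \code{(1 / (1 + exp(-(l - 10)/4))) * (0.1 + 1 / (1 + exp((l - 30)/15)))}.
#'
#' @param l Sound pressure level in dB.
#' @return Vector strength (non-negative).
#' @examples
#' vs_vs_level(20)
#' @export
vs_vs_level <- function(l) {
  (1.0 / (1 + exp(-(l - 10) / 4.0))) *
    (0.1 + 1.0 / (1 + exp((l - 30) / 15.0)))
}

## Deterministic splitting of one master seed into independent substreams.
## Simple multiplicative-congruential hash over doubles; all intermediates
## stay below 2^53 so the arithmetic is exact, results below 2^31.
derive_seed <- function(seed, ...) {
  h <- as.numeric(seed) %% 2147483647
  for (k in c(...)) {
    h <- (h * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(h)
}

## Bin indices (0-based) of the successes of a per-bin Bernoulli(p) process
## over n_bins bins, generated by geometric gaps. Exactly equivalent in
## distribution to flipping each bin independently, but only touches
## occupied bins.
bernoulli_bins <- function(n_bins, p) {
  if (p <= 0 || n_bins <= 0) return(numeric(0))
  if (p > 1) stop("per-bin probability exceeds 1; decrease dt")
  out <- list()
  pos <- -1   # last occupied bin
  i <- 1L
  while (pos < n_bins) {
    remaining <- n_bins - pos
    m <- ceiling(remaining * p + 4 * sqrt(remaining * p) + 16)
    gaps <- stats::rgeom(m, p) + 1
    bins <- pos + cumsum(gaps)
    out[[i]] <- bins
    pos <- bins[length(bins)]
    i <- i + 1L
  }
  bins <- unlist(out, use.names = FALSE)
  bins[bins < n_bins]
}

#' Generate a periodically modulated Poisson spike train
#'
#' Simulates one input fiber as an inhomogeneous Poisson process on a
#' discrete time grid, with intensity
#' \code{lambda(t) = rate * exp(k * cos(2 pi f_m t - phi)) / I0(k)},
#' i.e. a von Mises cycle histogram whose concentration k is chosen so that
#' the train's expected vector strength equals \code{vs}. The time-averaged
#' intensity equals \code{rate} for every k. For \code{f_m = 0} or
#' \code{vs = 0} the process is homogeneous Poisson at \code{rate}.
#'
#' Each grid bin of width \code{dt} independently contains a spike with
#' probability \code{lambda(t) dt} (generated sparsely, so large durations
#' are cheap).
#'
#' @param rate Mean rate in spikes/s (>= 0).
#' @param vs Target vector strength in [0, 1).
#' @param f_m Modulation frequency in Hz.
#' @param phase_offset Phase of the intensity peak in degrees; the intensity
#'   is maximal at \code{t = phase_offset / (360 f_m)}. Negative values
#'   advance the modulation (the peak occurs earlier).
#' @param duration Duration in seconds.
#' @param dt Time step in seconds (default 2e-6).
#' @param seed Optional integer seed (sets the RNG if given).
#' @return Numeric vector of strictly increasing spike times in
#'   [0, duration), aligned to the grid.
#' @examples
#' s <- generate_periodic_poisson(171, vs_vs_fm(300), 300, duration = 1,
#'                                seed = 1)
#' length(s)  # about 171
#' @export
generate_periodic_poisson <- function(rate, vs = 0, f_m = 0,
                                      phase_offset = 0, duration, dt = 2e-6,
                                      seed = NULL) {
  if (!is.numeric(rate) || rate < 0) stop("'rate' must be >= 0")
  if (vs < 0 || vs >= 1) stop("'vs' must lie in [0, 1)")
  stopifnot(duration > 0, dt > 0, f_m >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0) return(numeric(0))
  n_bins <- round(duration / dt)
  if (f_m == 0 || vs == 0) {
    bins <- bernoulli_bins(n_bins, rate * dt)
    return(bins * dt)
  }
  k <- vs_to_kappa(vs)
  ## peak intensity rate * exp(k)/I0(k); note I0(k) e^{-k} is the
  ## exponentially scaled Bessel, safe for large k
  lambda_max <- rate / besselI(k, 0, expon.scaled = TRUE)
  cand <- bernoulli_bins(n_bins, lambda_max * dt)
  if (length(cand) == 0) return(numeric(0))
  t <- cand * dt
  phi <- phase_offset * pi / 180
  accept <- stats::runif(length(t)) <
    exp(k * (cos(2 * pi * f_m * t - phi) - 1))
  t[accept]
}

#' Generate the full set of input spike trains for one trial
#'
#' Builds the excitatory and inhibitory input trains that drive one model
#' LSO neuron under a given stimulus, in one of three modes:
#' \describe{
#'   \item{\code{"monaural"}}{\code{n_exc} phase-locked excitatory fibers
#'     with rate \code{rate_vs_fm(f_m)} and vector strength
#'     \code{vs_vs_fm(f_m)} (all locked to the same stimulus phase,
#'     independent realizations), plus \code{n_inh} homogeneous spontaneous
#'     inhibitory fibers at \code{lambda_inh_spont}.}
#'   \item{\code{"binaural"}}{Excitation as above; inhibitory fibers are
#'     sound-evoked, with the same rate and phase-locking parameters as
#'     excitation but with their modulation advanced by
#'     \code{stim$phase_diff} degrees (positive = inhibition precedes
#'     excitation). Evoked inhibition replaces spontaneous inhibition by
#'     default; set \code{spont_inh = "add"} to keep an additional
#'     \code{n_inh} spontaneous fibers.}
#'   \item{\code{"level_driven"}}{Rates and vector strengths are taken from
#'     the level functions \code{rate_vs_level} / \code{vs_vs_level} at
#'     \code{stim$level_ipsi} (excitation) and \code{stim$level_contra}
#'     (inhibition). With \code{f_m = 0} the trains are homogeneous; with
#'     \code{f_m > 0} they are modulated and \code{phase_diff} (default 0)
#'     applies to inhibition as in binaural mode.}
#' }
#'
#' Each fiber draws from its own RNG substream derived deterministically
#' from \code{seed}, so changing the number of fibers does not perturb the
#' realizations of the remaining fibers.
#'
#' @param stim A \code{\link{stimulus_spec}}.
#' @param pop A \code{\link{fiber_population}}.
#' @param mode One of \code{"monaural"}, \code{"binaural"},
#'   \code{"level_driven"}.
#' @param seed Integer master seed.
#' @param spont_inh For binaural mode: \code{"replace"} (default) or
#'   \code{"add"} spontaneous inhibition alongside the evoked inhibition.
#' @param rate_fun,vs_fun Optional overrides for the modulation-frequency
#'   dependence of rate and vector strength; functions of \code{f_m} used in
#'   monaural/binaural mode (defaults \code{rate_vs_fm} with the
#'   population's \code{lambda0}, and \code{vs_vs_fm} with its
#'   \code{vs_max}). Used e.g. to hold the input rate or VS constant.
#' @return An object of class \code{"spike_train_set"}: a list with
#'   \code{exc_trains}, \code{inh_trains} (lists of spike-time vectors),
#'   \code{duration}, \code{dt}, \code{seed} and \code{mode}.
#' @examples
#' sts <- generate_input_set(stimulus_spec(f_m = 300, duration = 1),
#'                           fiber_population(), "monaural", seed = 1)
#' summary(sts)
#' @export
generate_input_set <- function(stim, pop, mode = c("monaural", "binaural",
                                                   "level_driven"),
                               seed, spont_inh = c("replace", "add"),
                               rate_fun = NULL, vs_fun = NULL) {
  mode <- match.arg(mode)
  spont_inh <- match.arg(spont_inh)
  stopifnot(inherits(stim, "stimulus_spec"),
            inherits(pop, "fiber_population"))
  if (mode == "binaural" && is.null(stim$phase_diff))
    stop("binaural mode requires 'phase_diff' in the stimulus spec")
  if (mode == "level_driven" &&
      (is.null(stim$level_ipsi) || is.null(stim$level_contra)))
    stop("level_driven mode requires 'level_ipsi' and 'level_contra'")
  lambda0 <- rep_len(pop$lambda0, pop$n_exc)

  exc_rate <- function(i) {
    switch(mode,
           level_driven = rate_vs_level(stim$level_ipsi),
           if (is.null(rate_fun)) rate_vs_fm(stim$f_m, lambda0[i])
           else rate_fun(stim$f_m))
  }
  exc_vs <- if (mode == "level_driven") vs_vs_level(stim$level_ipsi)
            else if (is.null(vs_fun)) vs_vs_fm(stim$f_m, pop$vs_max)
            else vs_fun(stim$f_m)

  exc <- lapply(seq_len(pop$n_exc), function(i)
    generate_periodic_poisson(exc_rate(i), exc_vs, stim$f_m,
                              phase_offset = 0,
                              duration = stim$duration, dt = stim$dt,
                              seed = derive_seed(seed, 1L, i)))

  pd <- if (is.null(stim$phase_diff)) 0 else stim$phase_diff
  inh <- switch(mode,
    monaural = lapply(seq_len(pop$n_inh), function(i)
      generate_periodic_poisson(pop$lambda_inh_spont, 0, 0,
                                duration = stim$duration, dt = stim$dt,
                                seed = derive_seed(seed, 2L, i))),
    binaural = lapply(seq_len(pop$n_inh), function(i)
      generate_periodic_poisson(
        if (is.null(rate_fun)) rate_vs_fm(stim$f_m, pop$lambda0[1L])
        else rate_fun(stim$f_m),
        if (is.null(vs_fun)) vs_vs_fm(stim$f_m, pop$vs_max)
        else vs_fun(stim$f_m),
        stim$f_m, phase_offset = -pd,
        duration = stim$duration, dt = stim$dt,
        seed = derive_seed(seed, 2L, i))),
    level_driven = lapply(seq_len(pop$n_inh), function(i)
      generate_periodic_poisson(rate_vs_level(stim$level_contra),
                                vs_vs_level(stim$level_contra),
                                stim$f_m, phase_offset = -pd,
                                duration = stim$duration, dt = stim$dt,
                                seed = derive_seed(seed, 2L, i))))
  if (mode == "binaural" && spont_inh == "add") {
    inh <- c(inh, lapply(seq_len(pop$n_inh), function(i)
      generate_periodic_poisson(pop$lambda_inh_spont, 0, 0,
                                duration = stim$duration, dt = stim$dt,
                                seed = derive_seed(seed, 3L, i))))
  }

  structure(list(exc_trains = exc, inh_trains = inh,
                 duration = stim$duration, dt = stim$dt, seed = seed,
                 mode = mode),
            class = "spike_train_set")
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat("Spike train set (", x$mode, " mode): ",
      length(x$exc_trains), " excitatory + ", length(x$inh_trains),
      " inhibitory fibers, ", x$duration, " s\n", sep = "")
  cat("  pooled rates:",
      round(sum(lengths(x$exc_trains)) / x$duration, 1), "exc,",
      round(sum(lengths(x$inh_trains)) / x$duration, 1),
      "inh spikes/s\n")
  invisible(x)
}

#' @export
summary.spike_train_set <- function(object, ...) print(object)
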