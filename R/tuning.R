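## Tuning analysis: modulation transfer functions, binaural phase tuning,
## ILD sweeps, and their summary metrics.

#' Vector strength of a spike train
#'
#' Resultant length of the spike phases relative to the modulation cycle:
#' \code{R = |sum(exp(1i 2 pi f_m t_j))| / n}. 1 indicates perfect
#' phase-locking, 0 a uniform phase distribution.
#'
#' @param spike_times Numeric vector of spike times in seconds.
#' @param f_m Modulation frequency in Hz (> 0).
#' @return R in [0, 1]; \code{NA} for an empty train (undefined, reported as
#'   missing rather than zero).
#' @examples
#' vector_strength(c(0, 1, 2) / 300, 300)   # 1: identical phases
#' @export
vector_strength <- function(spike_times, f_m) {
  stopifnot(f_m > 0)
  n <- length(spike_times)
  if (n == 0) return(NA_real_)
  ph <- 2 * pi * f_m * spike_times
  sqrt(sum(cos(ph))^2 + sum(sin(ph))^2) / n
}

#' Modulation gain
#'
#' The dB measure of output phase-locking used for synchrony MTFs:
#' \code{20 log10(2 R)}, where R is the output vector strength. A perfectly
#' modulated (half-wave) response has R = 0.5 and gain 0 dB.
#'
#' @param R Vector strength in [0, 1].
#' @return Gain in dB; \code{NA} for R = 0 (gain is -Inf, reported missing)
#'   and for missing R.
#' @examples
#' modulation_gain(0.5)   # 0 dB
#' modulation_gain(1)     # about 6.02 dB
#' @export
modulation_gain <- function(R) {
  ifelse(is.na(R) | R <= 0, NA_real_, 20 * log10(2 * R))
}

new_tuning_curve <- function(x, rate, gain = NULL, kind, xlab, duration,
                             params, f_m = NULL) {
  df <- data.frame(x = x, rate = rate)
  if (!is.null(gain)) df$gain <- gain
  structure(df, class = c("tuning_curve", "data.frame"),
            kind = kind, xlab = xlab, duration_per_point = duration,
            params = params, f_m = f_m)
}

#' @export
print.tuning_curve <- function(x, ...) {
  cat("Tuning curve (", attr(x, "kind"), "), ", nrow(x), " points, ",
      attr(x, "duration_per_point"), " s per point\n", sep = "")
  print.data.frame(x, ...)
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  graphics::plot(x$x, x$rate, type = "o", pch = 16, cex = 0.6,
                 xlab = attr(x, "xlab"), ylab = "Output rate (spikes/s)",
                 ...)
  invisible(x)
}

## Five-point smoothing: unweighted centered moving average over 5 adjacent
## grid points; endpoints averaged over the neighbors that exist.
smooth5 <- function(y) {
  n <- length(y)
  vapply(seq_len(n), function(i) {
    j <- max(1L, i - 2L):min(n, i + 2L)
    mean(y[j])
  }, numeric(1))
}

## Cubic spline interpolation of the smoothed curve on a fine grid.
interp_mtf <- function(x, y, step = 1) {
  xout <- seq(min(x), max(x), by = step)
  s <- stats::spline(x, y, xout = xout)
  list(x = s$x, y = s$y)
}

#' Compute a rate modulation transfer function (rate-MTF)
#'
#' Runs one trial per modulation frequency and records the mean output spike
#' rate (the rate-MTF) and the modulation gain of the output train (the
#' synchrony MTF). Each grid point uses an independent RNG substream derived
#' from \code{seed}.
#'
#' @param pop A \code{\link{fiber_population}}.
#' @param params Neuron parameters (coincidence or integrator).
#' @param fm_grid Modulation frequencies in Hz (default 25-1200 in 25 Hz
#'   steps).
#' @param duration Seconds simulated per grid point (default 100).
#' @param seed Integer master seed.
#' @param dt Time step in seconds.
#' @param mode Input mode (default \code{"monaural"}).
#' @param ... Passed to \code{\link{generate_input_set}} (e.g.
#'   \code{rate_fun}, \code{vs_fun} to hold input rate or VS constant).
#' @return A \code{"tuning_curve"} data frame with columns \code{x} (Hz),
#'   \code{rate} (spikes/s) and \code{gain} (dB).
#' @examples
#' \donttest{
#' mtf <- compute_rate_mtf(fiber_population(), coincidence_params(),
#'                         fm_grid = seq(100, 500, 100), duration = 5,
#'                         seed = 1)
#' monaural_metrics(mtf)
#' }
#' @export
compute_rate_mtf <- function(pop, params, fm_grid = seq(25, 1200, by = 25),
                             duration = 100, seed = 1, dt = 2e-6,
                             mode = "monaural", ...) {
  stopifnot(length(fm_grid) >= 1, all(diff(fm_grid) > 0))
  res <- lapply(seq_along(fm_grid), function(i) {
    stim <- stimulus_spec(f_m = fm_grid[i], duration = duration, dt = dt,
                          phase_diff = if (mode == "binaural") 0 else NULL)
    out <- run_trial(stim, pop, params, mode = mode,
                     seed = derive_seed(seed, 101L, i), ...)
    c(rate = output_rate(out),
      vs = vector_strength(out$spike_times, fm_grid[i]))
  })
  res <- do.call(rbind, res)
  new_tuning_curve(fm_grid, res[, "rate"], modulation_gain(res[, "vs"]),
                   kind = "rate_mtf", xlab = "Modulation frequency (Hz)",
                   duration = duration, params = params)
}

#' Summary metrics of a monaural rate-MTF
#'
#' Baseline is the lowest raw rate over the grid. Peak rate and frequency
#' are taken from the five-point-smoothed, spline-interpolated curve
#' (1 Hz resolution). The corner (half-peak) frequency is the highest
#' frequency at which the interpolated curve crosses
#' \code{baseline + 0.5 (peak - baseline)} on its descending flank.
#'
#' @param curve A \code{"tuning_curve"} from \code{\link{compute_rate_mtf}}
#'   (at least 5 grid points).
#' @return An object of class \code{"monaural_metrics"}: list with
#'   \code{peak_rate}, \code{peak_freq}, \code{baseline_rate},
#'   \code{corner_freq} (corner is \code{NA} for a flat curve).
#' @export
monaural_metrics <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"), nrow(curve) >= 5)
  baseline <- min(curve$rate)
  s <- interp_mtf(curve$x, smooth5(curve$rate))
  i_pk <- which.max(s$y)
  peak <- s$y[i_pk]
  freq <- s$x[i_pk]
  corner <- NA_real_
  if (peak > baseline) {
    lev <- baseline + 0.5 * (peak - baseline)
    dn <- which(s$y[-length(s$y)] >= lev & s$y[-1] < lev)
    if (length(dn)) {
      i <- dn[length(dn)]
      corner <- s$x[i] + (s$x[i + 1] - s$x[i]) *
        (s$y[i] - lev) / (s$y[i] - s$y[i + 1])
    }
  }
  structure(list(peak_rate = peak, peak_freq = freq,
                 baseline_rate = baseline, corner_freq = corner),
            class = "monaural_metrics")
}

#' @export
print.monaural_metrics <- function(x, ...) {
  cat(sprintf(
    "Monaural AM tuning: peak %.1f spikes/s at %.0f Hz, baseline %.1f, corner %.0f Hz\n",
    x$peak_rate, x$peak_freq, x$baseline_rate, x$corner_freq))
  invisible(x)
}

#' Compute a binaural phase-tuning curve
#'
#' Runs one binaural trial per phase difference between inhibitory and
#' excitatory input modulation (positive = inhibition precedes excitation)
#' and records the mean output rate. With \code{levels} supplied, the trial
#' is run in level-driven mode with the given (ipsi, contra) dB levels.
#'
#' @param pop A \code{\link{fiber_population}}.
#' @param params Neuron parameters.
#' @param f_m Modulation frequency in Hz (default 300).
#' @param phase_grid Phase differences in degrees covering one cycle
#'   (default 10 degree steps over (-180, 180]).
#' @param duration Seconds per point (default 100).
#' @param seed Integer master seed.
#' @param dt Time step in seconds.
#' @param levels Optional numeric c(level_ipsi, level_contra) in dB;
#'   switches the input generation to level-driven mode.
#' @param ... Passed to \code{\link{generate_input_set}}.
#' @return A \code{"tuning_curve"} with \code{x} in degrees and \code{rate}
#'   in spikes/s.
#' @examples
#' \donttest{
#' ptc <- compute_phase_tuning(fiber_population(), coincidence_params(),
#'                             phase_grid = seq(-150, 180, 30),
#'                             duration = 5, seed = 1)
#' binaural_metrics(ptc)
#' }
#' @export
compute_phase_tuning <- function(pop, params, f_m = 300,
                                 phase_grid = seq(-170, 180, by = 10),
                                 duration = 100, seed = 1, dt = 2e-6,
                                 levels = NULL, ...) {
  stopifnot(all(diff(phase_grid) > 0), f_m > 0)
  mode <- if (is.null(levels)) "binaural" else "level_driven"
  rate <- vapply(seq_along(phase_grid), function(i) {
    stim <- stimulus_spec(f_m = f_m,
                          level_ipsi = levels[1], level_contra = levels[2],
                          phase_diff = phase_grid[i],
                          duration = duration, dt = dt)
    output_rate(run_trial(stim, pop, params, mode = mode,
                          seed = derive_seed(seed, 202L, i), ...))
  }, numeric(1))
  new_tuning_curve(phase_grid, rate, kind = "phase_tuning",
                   xlab = "Phase difference (deg)", duration = duration,
                   params = params, f_m = f_m)
}

## Circular five-point smoothing: centered moving average with wrap-around.
smooth5_circ <- function(y) {
  n <- length(y)
  yy <- c(y[c(n - 1, n)], y, y[c(1, 2)])
  vapply(seq_len(n), function(i) mean(yy[i:(i + 4)]), numeric(1))
}

## Periodic cubic spline of a phase-tuning curve on a 1-degree grid.
## Returns phases mapped into (-180, 180].
interp_phase <- function(x, y, step = 1) {
  xx <- c(x, x[1] + 360)
  yy <- c(y, y[1])
  xout <- seq(x[1], x[1] + 360 - step, by = step)
  s <- stats::spline(xx, yy, method = "periodic", xout = xout)
  ph <- ((s$x + 180) %% 360) - 180
  ph[ph == -180] <- 180
  o <- order(ph)
  list(x = ph[o], y = s$y[o])
}

#' Summary metrics of a binaural phase-tuning curve
#'
#' The curve is five-point smoothed (circularly, mirroring the smoothing
#' used for rate-MTF metrics) and interpolated with a periodic cubic spline
#' at 1 degree resolution, treating phase as circular; peak and trough rates
#' and phases are read from the interpolated curve. Without smoothing, the
#' flat-bottomed trough of a stochastic curve would make the extracted
#' trough phase noise-dominated. The
#' half-peak width is the circular extent (in degrees) of the trough region
#' delimited by the two crossings of the half-peak level
#' \code{trough + 0.5 (peak - trough)} (the level is measured from the
#' trough): the arc over which the interpolated rate stays below half-peak.
#' For a pure cosine curve this is 180 degrees.
#'
#' @param curve A \code{"tuning_curve"} from
#'   \code{\link{compute_phase_tuning}} spanning a full cycle.
#' @return An object of class \code{"binaural_metrics"}: list with
#'   \code{peak_rate}, \code{peak_phase}, \code{trough_rate},
#'   \code{trough_phase} (degrees in (-180, 180]), \code{half_peak_width}
#'   (degrees), and \code{trough_ms} (trough position converted to ms, using
#'   the curve's modulation frequency; \code{NA} when unknown). For a flat
#'   curve the phases are \code{NA}.
#' @export
binaural_metrics <- function(curve) {
  stopifnot(inherits(curve, "tuning_curve"))
  s <- interp_phase(curve$x, smooth5_circ(curve$rate))
  i_pk <- which.max(s$y)
  i_tr <- which.min(s$y)
  peak <- s$y[i_pk]; trough <- s$y[i_tr]
  flat <- (peak - trough) < sqrt(.Machine$double.eps)
  lev <- trough + 0.5 * (peak - trough)
  width <- sum(s$y < lev) * (s$x[2] - s$x[1])
  f_m <- attr(curve, "f_m")
  trough_phase <- if (flat) NA_real_ else s$x[i_tr]
  structure(list(
    peak_rate = peak,
    peak_phase = if (flat) NA_real_ else s$x[i_pk],
    trough_rate = trough,
    trough_phase = trough_phase,
    half_peak_width = if (flat) NA_real_ else width,
    trough_ms = if (is.null(f_m) || flat) NA_real_
                else trough_phase / 360 * 1000 / f_m),
    class = "binaural_metrics")
}

#' @export
print.binaural_metrics <- function(x, ...) {
  cat(sprintf(
    "Binaural phase tuning: peak %.1f spikes/s at %+.0f deg, trough %.1f at %+.0f deg, half-peak width %.0f deg\n",
    x$peak_rate, x$peak_phase, x$trough_rate, x$trough_phase,
    x$half_peak_width))
  invisible(x)
}

#' Predicted trough position from the window widths
#'
#' The trough of a binaural phase-tuning curve (maximal
#' excitatory-inhibitory coincidence) is predicted at half the difference of
#' the inhibition and coincidence windows: \code{P_T = (Delta - W) / 2}.
#'
#' @param W Coincidence window in seconds.
#' @param Delta Inhibition window in seconds.
#' @return Predicted trough position in milliseconds (positive = inhibition
#'   leading).
#' @examples
#' predicted_trough(0.8e-3, 1.6e-3)  # 0.4 ms
#' @export
predicted_trough <- function(W, Delta) {
  stopifnot(all(W > 0), all(Delta > 0))
  (Delta - W) / 2 * 1000
}

#' Compute an interaural level difference (ILD) sweep
#'
#' Runs level-driven trials at a fixed ipsilateral level while varying the
#' contralateral level, recording the mean output rate versus
#' ILD = level_contra - level_ipsi (positive = inhibition-driving side
#' louder).
#'
#' @param pop A \code{\link{fiber_population}}.
#' @param params Neuron parameters.
#' @param level_ipsi Ipsilateral level in dB.
#' @param ild_grid ILD values in dB (contra = ipsi + ILD).
#' @param f_m Modulation frequency in Hz (0 = unmodulated).
#' @param phase_diff Phase difference in degrees when \code{f_m > 0}.
#' @param duration Seconds per point.
#' @param seed Integer master seed.
#' @param dt Time step in seconds.
#' @return A \code{"tuning_curve"} with \code{x} = ILD (dB).
#' @export
compute_ild_curve <- function(pop, params, level_ipsi = 20,
                              ild_grid = seq(-20, 20, 5), f_m = 0,
                              phase_diff = 0, duration = 100, seed = 1,
                              dt = 2e-6) {
  rate <- vapply(seq_along(ild_grid), function(i) {
    stim <- stimulus_spec(f_m = f_m, level_ipsi = level_ipsi,
                          level_contra = level_ipsi + ild_grid[i],
                          phase_diff = phase_diff,
                          duration = duration, dt = dt)
    output_rate(run_trial(stim, pop, params, mode = "level_driven",
                          seed = derive_seed(seed, 303L, i)))
  }, numeric(1))
  new_tuning_curve(ild_grid, rate, kind = "ild", xlab = "ILD (dB)",
                   duration = duration, params = params,
                   f_m = if (f_m > 0) f_m else NULL)
}
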