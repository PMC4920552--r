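---
title: "Coincidence counting in the lateral superior olive: model, inputs and tuning analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coincidence counting in the lateral superior olive}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsocoin)
```

## The scientific problem

Principal neurons of the lateral superior olive (LSO) receive excitatory
inputs driven by the ipsilateral ear (via bushy cells of the ventral
cochlear nucleus) and inhibitory inputs driven by the contralateral ear
(via the medial nucleus of the trapezoid body, MNTB). They encode
interaural level differences (ILDs), but they are also sensitive to the
temporal structure of amplitude-modulated (AM) sounds, both monaurally
(their firing rate is tuned to the envelope modulation frequency) and
binaurally (their rate varies periodically with the phase difference
between the two ears' envelopes, with a characteristic *trough* where
excitation and inhibition coincide — "anticoincidence" tuning).

`lsocoin` implements a deliberately minimal model of this computation: the
neuron is a *coincidence counter* rather than a biophysical compartment
model. The package provides (i) stochastic generators for the phase-locked
input spike trains, (ii) the coincidence-counting neuron and a
pure-integrator control, and (iii) the tuning analyses (modulation transfer
functions, phase-tuning curves, ILD sweeps) with the summary metrics used
to characterize them.

## Input model

Each excitatory fiber is an inhomogeneous Poisson process with intensity

$$\lambda(t) \;=\; \bar\lambda \, \frac{\exp\!\big(k \cos(2\pi f_m t - \varphi)\big)}{I_0(k)},$$

a von Mises (circular normal) cycle histogram around the envelope period.
The concentration $k$ is chosen by inverting the Bessel ratio
$\mathrm{VS} = I_1(k)/I_0(k)$ (`vs_to_kappa`), so the train's expected
vector strength equals the requested VS; the time-averaged intensity is
$\bar\lambda$ for every $k$. Rate and phase-locking of the input fibers
depend on modulation frequency as

$$\bar\lambda(f_m) = \lambda_0 - 0.03 f_m \quad\text{(spikes/s, floored at 0)},
\qquad \mathrm{VS}(f_m) = 0.65\,\tanh\!\big((2000 - f_m)/1000\big),$$

which reach typical bushy-cell values ($\lambda_0 = 180$ spikes/s,
VS just under 0.65 at low $f_m$) and zero phase-locking at 2000 Hz. For
level-driven simulations, rate and VS instead follow sigmoidal functions of
sound pressure level ($\bar\lambda(20\,\mathrm{dB}) = 150$ spikes/s at the
ILD = 0 operating point), shared by excitatory and inhibitory fibers.

By default 20 excitatory fibers are locked to the same stimulus phase
(identical parameters, independent realizations — no fiber-to-fiber phase
jitter) and 8 inhibitory fibers are spontaneously active homogeneous
Poisson processes at 30 spikes/s. In binaural simulations the inhibitory
fibers are instead sound-evoked with the same rate and VS functions as the
excitation, their modulation advanced by the phase difference (positive =
inhibition precedes excitation). Evoked inhibition *replaces* spontaneous
inhibition; whether the spontaneous component persists during driven
activity is not constrained by the data we emulate, so replacement is the
default and `spont_inh = "add"` is available as an option.

### Generation scheme

Trains are generated on a discrete grid (default `dt` = 2 µs): each bin
independently contains a spike with probability $\lambda(t)\,dt$. The
implementation enumerates only occupied bins: successes of a
Bernoulli($p_{\max}$) process are produced by geometric gaps and thinned
with probability $\lambda(t)/\lambda_{\max}$, which is exactly equivalent
in distribution and makes 100 s trials cheap. Results are insensitive to
the grid: statistics at `dt` = 1 µs match those at 2 µs (tested), and the
neuron models produce *identical* output spike sets under grid refinement
because their state only changes at input events.

Each fiber draws from its own RNG substream derived deterministically from
the master seed, so enlarging the population does not perturb the
realizations of existing fibers, and every simulation is exactly
reproducible from its seed.

## The coincidence-counting neuron

The model has five parameters (`coincidence_params`, defaults in
parentheses): coincidence threshold $\theta$ (8 inputs), coincidence window
$W$ (0.8 ms), refractory period $T$ (1.6 ms), inhibition window $\Delta$
(1.6 ms) and threshold increase $\delta$ (2 inputs). A trailing window
$(t-W,\,t]$ slides along the grid; an output spike is emitted at the first
bin where the pooled excitatory count reaches the *effective threshold*

$$\theta(t) \;=\; \theta + \delta \times \#\{\text{inhibitory spikes in } (t-\Delta,\, t]\},$$

provided at least $T$ has elapsed since the previous output spike;
super-threshold candidates inside the refractory period are discarded
(only the first spike counts). Elevations from overlapping inhibitory
spikes add, which is what makes the time-averaged elevation equal
$M_\mathrm{inh}\,\lambda_\mathrm{inh}\,\Delta\,\delta = 8 \times 30 \times
1.6\times10^{-3} \times 2 = 0.768$ inputs under spontaneous inhibition —
less than lowering $\theta$ by one, which is why spontaneous inhibition
barely affects monaural tuning.

Numerical conventions that the data do not pin down, fixed here once:

* **Window anchoring.** The sliding window is trailing and half-open,
  $(t-W, t]$, so an output spike time coincides with the input spike that
  completes the coincidence. The inhibition window likewise covers
  $[t_\mathrm{inh},\, t_\mathrm{inh}+\Delta)$ on the grid.
* **Re-triggering.** The per-bin rule emits at every eligible bin where the
  count is super-threshold; with the defaults ($T \ge W$) a sustained
  super-threshold count cannot re-trigger within one window, but the rule
  is defined for all parameter values.
* **No burn-in.** Trials start cold at $t = 0$; with 100 s trials the edge
  effect is below 0.01 %.

The implementation is event-driven (the window count and the effective
threshold are piecewise constant between input arrivals and expiries) and
is verified in the test suite against a brute-force per-bin oracle by
exhaustive window recounting on dozens of random small instances, with
exact agreement of output spike sets required.

## The pure-integrator control

The control model (`integrator_params`) drops all temporal windows: it
counts excitatory and inhibitory inputs since the end of the last
refractory period and fires when $N_e - \delta N_i \ge \theta$, then resets
and ignores inputs for $T$. The running difference may go negative (excess
inhibition); no floor is applied, since a floor would change binaural
behaviour and nothing in the reference behaviour requires one. Inputs
arriving *during* the refractory period are discarded rather than banked —
the model is in a refractory state, and counting resumes when it ends.
Inputs sharing an arrival time are accumulated before the threshold test,
matching the continuous-time definition.

Because only counts matter, clustering eight excitatory spikes inside one
millisecond or spreading them over tens of milliseconds yields the same
integrator output, while the coincidence counter fires only in the former
case — this contrast is the defining property, and it is what makes the
integrator's rate tuning nearly all-pass (flat above 300 Hz) where the
coincidence counter is band-pass. One caveat worth stating: "timing never
matters" holds only *within* an integration epoch and *before* the
threshold crossing. Inhibition arriving after the crossing cannot
retroactively cancel it (the spike has fired and the counters reset), so
early inhibition cancels late excitation but not vice versa; the test
suite exercises exactly this asymmetry.

## Tuning analyses and metrics

**Rate- and synchrony-MTFs** (`compute_rate_mtf`): one trial per
modulation frequency on a 25–1200 Hz grid in 25 Hz steps (fine enough to
resolve the ~265 Hz peak under five-point smoothing), 100 s per point by
default; the output rate gives the rate-MTF and the output vector strength
gives the modulation gain $20\log_{10}(2R)$ of the synch-MTF.

**Monaural metrics** (`monaural_metrics`): the baseline is the minimum of
the *raw* curve over the grid (smoothing would drag the extreme value
toward its neighbours, biasing the baseline up); peak rate and frequency
are taken from the five-point-smoothed, cubic-spline-interpolated curve on
a 1 Hz grid; the corner (half-peak) frequency is the highest crossing of
$\mathrm{baseline} + \tfrac12(\mathrm{peak}-\mathrm{baseline})$ on the
descending flank, the "frequency limit" of the tuning curve. Five-point
smoothing is an unweighted centered moving average (endpoints averaged
over the neighbours that exist); the spline is the standard cubic
interpolant evaluated at 1 Hz.

**Phase-tuning curves** (`compute_phase_tuning`): binaural trials on a 10°
grid over (−180°, 180°]. Metrics (`binaural_metrics`) are extracted from a
circularly five-point-smoothed, periodic-cubic-spline interpolation at 1°
resolution — the same smoothing-plus-spline procedure as for the monaural
curve, applied with wrap-around. The smoothing matters here: the default
curve has a flat-bottomed trough (the inhibition window fully covers the
coincidence window over a ~20–30° span), and the argmin of an unsmoothed
interpolated stochastic curve would wander over that span from realization
to realization. The **half-peak width** is the circular extent of the
trough region delimited by the two crossings of the half-peak level
$\mathrm{trough} + \tfrac12(\mathrm{peak}-\mathrm{trough})$ (for a pure
cosine curve: 180°). The trough position in milliseconds is
$\mathrm{phase}/360 \cdot 1000/f_m$, and its predicted value is
$P_T = (\Delta - W)/2$ (`predicted_trough`): the phase response is shifted
by half the width difference of the two windows, because that delay makes
the combined excitatory/inhibitory window function temporally symmetric.

**ILD sweeps** (`compute_ild_curve`, experiments `fig13a`/`fig13bc`):
level-driven trials with ILD defined as contralateral minus ipsilateral
level (positive = inhibition-driving side louder); the phase-tuning ILD
experiment holds the arithmetic-mean binaural level at 20 dB, the 150
spikes/s per-fiber operating point.

## Experiment drivers

`run_experiment(experiment_config(id, ...))` reproduces the standard
sweeps end-to-end (see `lso_experiments()` for the ids): threshold, window,
refractory and inhibition sweeps; covariation of $\theta$ and $W$ at fixed
ratio; window calibration to matched peak rate
(`fig7_window_calibration`, a deterministic bisection over $W$ with a
fixed per-evaluation seed, reporting thresholds for which no window in
[0.1, 2.0] ms attains the band); heterogeneous input intensities (ten
draws of per-fiber $\lambda_0 \sim \mathrm{Uniform}(80, 280)$ spikes/s);
trough-position laws; ILD experiments; and the integrator control. Each
run returns tidy tables plus a manifest (parameters, seeds, package
version), and identical configurations reproduce identical tables.

## A worked example

A reduced-duration run (2 s per point here; use 100 s for production-grade
estimates):

```{r example, eval = FALSE}
library(lsocoin)
pop <- fiber_population()
mtf <- compute_rate_mtf(pop, coincidence_params(), duration = 2, seed = 1)
monaural_metrics(mtf)
ptc <- compute_phase_tuning(pop, coincidence_params(), duration = 2, seed = 1)
binaural_metrics(ptc)
```

At the full 100 s per point the default configuration yields a band-pass
rate-MTF with peak ≈ 138 spikes/s near 265 Hz, baseline ≈ 9–10 spikes/s
and corner ≈ 550 Hz, and a phase-tuning curve at 300 Hz with peak
≈ 128–131 spikes/s near −137°, trough ≈ 19–20 spikes/s near +44°, and a
half-peak width ≈ 189–191° — the values recomputed by
`scripts/acceptance.R`.

## Problem sizes, runtime and what the tests show

The package's own test and acceptance runs use the full 100 s per
condition point for the quantitative tuning metrics (a 100 s trial is
about a quarter second of compute) and reduced durations of 20–30 s per
point for qualitative regime checks (monotonic high-threshold tuning,
second peak for wide windows, flat-to-tuned transition with the threshold
increase, integrator all-pass), where only coarse contrasts are asserted.

The synthetic inputs are idealized: Poisson statistics with a stationary
von Mises cycle histogram, no refractoriness in the input fibers, no
adaptation, no cochlear filtering or carrier fine structure, and identical
locking phase across fibers. Passing tests therefore show that the
*models and analyses* behave as specified under these stated input
statistics — not that real LSO inputs satisfy them; in particular the
model's phase-locking above ~1000 Hz is better than real neurons', which
lack-of-membrane-filtering makes unavoidable in a counting model.

## Known limitations

* No conductances, membrane dynamics or dynamic threshold adaptation — the
  abstraction is the point, but it restricts applicability to envelope
  frequencies below about 1000 Hz.
* Inhibition acts purely as a threshold elevation; subtractive or shunting
  inhibition would interact with excitation differently.
* The exact spline family for metric interpolation is a convention (cubic
  here); peak/corner estimates shift by only a few Hz for natural
  alternatives, well inside the stochastic scatter.
* Whether the inhibition window includes its left endpoint is a grid-level
  convention (included here); at `dt` = 2 µs the effect is negligible.
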