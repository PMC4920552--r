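test_that("effective threshold trace reflects pooled inhibition", {
  prm <- coincidence_params()   # theta 8, delta 2, Delta 1.6 ms
  dt <- 1e-4
  ## no inhibition: constant theta
  expect_equal(effective_threshold_trace(list(), prm, 0.01, dt),
               rep(8, 100))
  ## single spike: theta + delta over [t0, t0 + Delta)
  tr <- effective_threshold_trace(list(2e-3), prm, 0.01, dt)
  bin <- function(t) round(t / dt) + 1L   # 1-based bin index at time t
  want <- rep(8, 100)
  want[bin(2e-3):(bin(2e-3 + prm$Delta) - 1L)] <- 10
  expect_equal(tr, want)
  ## overlapping spikes add
  tr2 <- effective_threshold_trace(list(2e-3, 2.5e-3), prm, 0.01, dt)
  expect_equal(max(tr2), 12)
  expect_equal(tr2[bin(2.6e-3)], 12)
  expect_equal(tr2[bin(3.7e-3)], 10)  # first spike's window expired
})

test_that("time-averaged spontaneous inhibition elevates threshold by 0.768", {
  prm <- coincidence_params()
  ## closed form: 8 fibers x 30 spikes/s x 1.6 ms x 2
  expect_equal(8 * 30 * prm$Delta * prm$delta, 0.768)
  ## long-run simulated average agrees within 1%
  pop <- fiber_population()
  sts <- generate_input_set(stimulus_spec(f_m = 300, duration = 100),
                            pop, "monaural", seed = 21)
  elev <- mean_threshold_elevation(sts$inh_trains, prm, 100)
  expect_lt(abs(elev - 0.768) / 0.768, 0.01)
  ## and the exact interval arithmetic matches the explicit trace
  short <- lapply(sts$inh_trains, function(s) s[s < 2])
  tr <- effective_threshold_trace(short, prm, 2, 1e-5)
  expect_equal(mean(tr - prm$theta),
               mean_threshold_elevation(short, prm, 2), tolerance = 1e-3)
})

test_that("counter handles degenerate inputs and threshold-1 passthrough", {
  prm1 <- coincidence_params(theta = 1, delta = 0)
  empty <- list(exc_trains = list(), inh_trains = list(), duration = 0.1,
                dt = 2e-6)
  expect_length(run_coincidence_counter(empty, prm1)$spike_times, 0)
  one <- list(exc_trains = list(10e-3), inh_trains = list(),
              duration = 0.1, dt = 2e-6)
  out <- run_coincidence_counter(one, prm1)
  expect_equal(out$spike_times, 10e-3)
  expect_error(run_coincidence_counter(
    list(exc_trains = list(c(0.02, 0.01)), inh_trains = list(),
         duration = 0.1, dt = 2e-6), prm1), "sorted")
  expect_error(run_coincidence_counter(
    list(exc_trains = list(0.2), inh_trains = list(), duration = 0.1,
         dt = 2e-6), prm1), "duration")
})

test_that("a second qualifying coincidence inside T is rejected", {
  ## three spikes within one window fire at the third; a second qualifying
  ## event 1.0 ms later is inside T = 1.6 ms and is discarded
  prm <- coincidence_params(theta = 3, W = 0.8e-3, T = 1.6e-3, delta = 0)
  exc <- c(10.0e-3, 10.2e-3, 10.4e-3,   # first coincidence at 10.4 ms
           11.0e-3, 11.2e-3, 11.4e-3,   # would fire at 11.4 ms: rejected
           12.6e-3, 12.8e-3, 13.0e-3)   # fires again at 13.0 ms (>= T later)
  out <- run_coincidence_counter(
    list(exc_trains = list(exc), inh_trains = list(), duration = 0.05,
         dt = 2e-6), prm)
  expect_equal(out$spike_times, c(10.4e-3, 13.0e-3))
  expect_gte(out$n_candidate_coincidences, 3)
})

test_that("inhibition vetoes coincidences through the threshold elevation", {
  prm <- coincidence_params(theta = 3, W = 0.8e-3, T = 1.6e-3,
                            Delta = 1.6e-3, delta = 2)
  exc <- c(10.0e-3, 10.2e-3, 10.4e-3)
  base <- list(exc_trains = list(exc), inh_trains = list(),
               duration = 0.05, dt = 2e-6)
  expect_length(run_coincidence_counter(base, prm)$spike_times, 1)
  ## an inhibitory spike just before raises the threshold to 5: no output
  veto <- base; veto$inh_trains <- list(9.5e-3)
  expect_length(run_coincidence_counter(veto, prm)$spike_times, 0)
  ## the same inhibitory spike arriving after its window expired: output
  late <- base; late$inh_trains <- list(8.7e-3)
  expect_length(run_coincidence_counter(late, prm)$spike_times, 1)
})

test_that("sliding-window counter matches the brute-force per-bin oracle", {
  for (seed in 1:20) {
    inst <- random_cc_instance(seed)
    got <- run_cc(inst)$spike_times
    want <- oracle_counter(inst$exc, inst$inh, inst$duration, inst$dt,
                           inst$params)
    expect_equal(got, want, info = paste("instance", seed))
  }
})

test_that("output spike trains respect the refractory period", {
  sts <- generate_input_set(stimulus_spec(f_m = 100, duration = 20),
                            fiber_population(), "monaural", seed = 31)
  for (T_ref in c(0.8e-3, 1.6e-3, 2.4e-3)) {
    out <- run_coincidence_counter(sts, coincidence_params(T = T_ref))
    expect_gte(min(diff(out$spike_times)), T_ref - 1e-12)
    expect_true(all(out$spike_times >= 0 & out$spike_times < 20))
  }
})

test_that("without refractory interaction the accepted set shrinks with theta", {
  sts <- generate_input_set(stimulus_spec(f_m = 300, duration = 5),
                            fiber_population(), "monaural", seed = 32)
  dt <- 2e-6
  prev <- NULL
  for (th in 5:9) {
    prm <- coincidence_params(theta = th, T = dt)  # T -> one bin
    out <- run_coincidence_counter(sts, prm)$spike_times
    if (!is.null(prev)) expect_true(all(out %in% prev))
    prev <- out
  }
})

test_that("counter output is invariant to halving the time step", {
  sts <- generate_input_set(stimulus_spec(f_m = 300, duration = 10,
                                          phase_diff = 45),
                            fiber_population(), "binaural", seed = 33)
  prm <- coincidence_params()
  a <- run_coincidence_counter(sts, prm, dt = 2e-6)
  b <- run_coincidence_counter(sts, prm, dt = 1e-6)
  expect_identical(a$spike_times, b$spike_times)
})

test_that("identical seeds give identical trials", {
  stim <- stimulus_spec(f_m = 300, duration = 2)
  a <- run_trial(stim, fiber_population(), coincidence_params(),
                 "monaural", seed = 34)
  b <- run_trial(stim, fiber_population(), coincidence_params(),
                 "monaural", seed = 34)
  expect_identical(a$spike_times, b$spike_times)
})

test_that("spontaneous inhibition changes rates less than lowering theta by one", {
  stim <- stimulus_spec(f_m = 300, duration = 25)
  pop <- fiber_population()
  r_with <- output_rate(run_trial(stim, pop, coincidence_params(),
                                  "monaural", seed = 35))
  r_no_inh <- output_rate(run_trial(stim, pop,
                                    coincidence_params(delta = 0),
                                    "monaural", seed = 35))
  r_theta7 <- output_rate(run_trial(stim, pop,
                                    coincidence_params(theta = 7),
                                    "monaural", seed = 35))
  expect_lt(abs(r_with - r_no_inh), abs(r_theta7 - r_with))
})
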