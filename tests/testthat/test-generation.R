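test_that("degenerate and invalid generator inputs are handled", {
  expect_identical(generate_periodic_poisson(0, duration = 1, seed = 1),
                   numeric(0))
  expect_error(generate_periodic_poisson(-5, duration = 1), ">= 0")
  expect_error(generate_periodic_poisson(100, vs = 1, duration = 1),
               "0, 1")
})

test_that("homogeneous generation has Poisson-consistent counts and valid times", {
  s <- generate_periodic_poisson(180, 0, 0, duration = 100, seed = 11)
  n <- length(s)
  ## 99% two-sided Poisson interval around 18000
  expect_gt(n, qpois(0.005, 18000))
  expect_lt(n, qpois(0.995, 18000))
  expect_true(all(s >= 0 & s < 100))
  expect_true(all(diff(s) > 0))
})

test_that("modulated trains recover the target rate and vector strength", {
  f_m <- 300
  rate <- rate_vs_fm(f_m)
  vs <- vs_vs_fm(f_m)
  s <- generate_periodic_poisson(rate, vs, f_m, duration = 100, seed = 2)
  n <- length(s)
  expect_lt(abs(n - rate * 100), 3 * sqrt(rate * 100))
  expect_lt(abs(vector_strength(s, f_m) - vs), 0.02)
  ## time-averaged intensity stays at rate also for strong locking
  s2 <- generate_periodic_poisson(100, 0.9, 600, duration = 100, seed = 3)
  expect_lt(abs(length(s2) - 1e4), 3 * sqrt(1e4))
  expect_lt(abs(vector_strength(s2, 600) - 0.9), 0.02)
})

test_that("time-rescaled spike times form a unit-rate Poisson process", {
  ## spike times sit on the grid; spread each uniformly within its bin to
  ## remove discretization ties before the KS test
  dejitter <- function(s, dt = 2e-6) s + runif(length(s), 0, dt)
  ## homogeneous: intervals exponential
  s <- generate_periodic_poisson(200, 0, 0, duration = 60, seed = 4)
  expect_gt(length(s), 1e4)
  ks <- stats::ks.test(diff(dejitter(s)) * 200, "pexp", 1)
  expect_gt(ks$p.value, 0.01)
  ## modulated: transform by the cumulative intensity first
  f_m <- 300
  s <- generate_periodic_poisson(200, 0.6, f_m, duration = 60, seed = 5)
  tau <- cumulative_intensity(dejitter(s), 200, 0.6, f_m)
  ks <- stats::ks.test(diff(tau), "pexp", 1)
  expect_gt(ks$p.value, 0.01)
})

test_that("results are insensitive to refining the time step", {
  f_m <- 300
  rate <- rate_vs_fm(f_m)
  vs <- vs_vs_fm(f_m)
  a <- generate_periodic_poisson(rate, vs, f_m, duration = 100, dt = 2e-6,
                                 seed = 6)
  b <- generate_periodic_poisson(rate, vs, f_m, duration = 100, dt = 1e-6,
                                 seed = 6)
  se <- sqrt(rate * 100)
  expect_lt(abs(length(a) - length(b)), 3 * sqrt(2) * se)
  expect_lt(abs(vector_strength(a, f_m) - vector_strength(b, f_m)), 0.03)
})

test_that("input sets have the specified composition and rates", {
  stim <- stimulus_spec(f_m = 300, duration = 20)
  pop <- fiber_population()
  sts <- generate_input_set(stim, pop, "monaural", seed = 7)
  expect_length(sts$exc_trains, 20)
  expect_length(sts$inh_trains, 8)
  pooled_rate <- sum(lengths(sts$exc_trains)) / 20
  expect_lt(abs(pooled_rate - 20 * rate_vs_fm(300)),
            3 * sqrt(20 * rate_vs_fm(300) / 20))
  inh_rate <- sum(lengths(sts$inh_trains)) / 20
  expect_lt(abs(inh_rate - 8 * 30), 3 * sqrt(8 * 30 / 20))

  ## binaural with zero phase difference: excitation and inhibition share
  ## the modulation phase (circular means agree)
  stim_b <- stimulus_spec(f_m = 300, duration = 20, phase_diff = 0)
  sb <- generate_input_set(stim_b, pop, "binaural", seed = 7)
  mean_phase <- function(tr) {
    ph <- 2 * pi * 300 * unlist(tr)
    atan2(mean(sin(ph)), mean(cos(ph)))
  }
  dphi <- (mean_phase(sb$exc_trains) - mean_phase(sb$inh_trains))
  dphi <- atan2(sin(dphi), cos(dphi)) * 180 / pi
  expect_lt(abs(dphi), 5)
  ## positive phase difference advances inhibition (inhibition earlier)
  stim_a <- stimulus_spec(f_m = 300, duration = 20, phase_diff = 90)
  sa <- generate_input_set(stim_a, pop, "binaural", seed = 7)
  dphi_a <- mean_phase(sa$exc_trains) - mean_phase(sa$inh_trains)
  dphi_a <- atan2(sin(dphi_a), cos(dphi_a)) * 180 / pi
  expect_lt(abs(dphi_a - 90), 10)

  ## level-driven at 20/20 dB: both populations near 150 spikes/s per fiber
  stim_l <- stimulus_spec(f_m = 0, level_ipsi = 20, level_contra = 20,
                          duration = 20)
  sl <- generate_input_set(stim_l, pop, "level_driven", seed = 7)
  expect_lt(abs(mean(lengths(sl$exc_trains)) / 20 - 150),
            3 * sqrt(150 / 20 / 20))
  expect_lt(abs(mean(lengths(sl$inh_trains)) / 20 - 150),
            3 * sqrt(150 / 20 / 8))
})

test_that("per-fiber seeding is stable under population changes", {
  stim <- stimulus_spec(f_m = 300, duration = 5)
  a <- generate_input_set(stim, fiber_population(n_exc = 20), "monaural",
                          seed = 9)
  b <- generate_input_set(stim, fiber_population(n_exc = 10), "monaural",
                          seed = 9)
  expect_identical(a$exc_trains[1:10], b$exc_trains[1:10])
  expect_identical(a$inh_trains, b$inh_trains)
})

test_that("mode prerequisites are validated", {
  stim <- stimulus_spec(f_m = 300, duration = 1)
  pop <- fiber_population()
  expect_error(generate_input_set(stim, pop, "binaural", seed = 1),
               "phase_diff")
  expect_error(generate_input_set(stim, pop, "level_driven", seed = 1),
               "level")
})
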