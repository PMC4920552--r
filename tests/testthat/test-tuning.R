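test_that("vector strength matches its defining cases", {
  expect_equal(vector_strength(c(0, 1, 2, 3) / 300, 300), 1)
  ## four spikes at quadrature phases cancel
  expect_equal(vector_strength(c(0, 0.25, 0.5, 0.75) / 300, 300), 0,
               tolerance = 1e-12)
  expect_true(is.na(vector_strength(numeric(0), 300)))
  ## law of large numbers: von Mises phases at k for VS 0.65
  set.seed(51)
  k <- vs_to_kappa(0.65)
  ## draw via rejection from the wrapped density
  n <- 1e5
  draws <- numeric(0)
  while (length(draws) < n) {
    x <- runif(2 * n, -pi, pi)
    u <- runif(2 * n)
    draws <- c(draws, x[u < exp(k * (cos(x) - 1))])
  }
  ph <- draws[seq_len(n)] / (2 * pi * 300)
  expect_lt(abs(vector_strength(ph, 300) - 0.65), 0.01)
})

test_that("modulation gain is 20 log10(2R)", {
  expect_equal(modulation_gain(0.5), 0)
  expect_equal(modulation_gain(1), 20 * log10(2))
  expect_equal(modulation_gain(0.25), -20 * log10(2))
  expect_true(is.na(modulation_gain(0)))
  expect_true(is.na(modulation_gain(NA)))
})

synthetic_curve <- function(x, rate) {
  structure(data.frame(x = x, rate = rate),
            class = c("tuning_curve", "data.frame"),
            kind = "rate_mtf", xlab = "Hz", duration_per_point = NA,
            params = NULL)
}

test_that("monaural metrics recover known synthetic curve features", {
  x <- seq(25, 1200, by = 25)
  ## triangular curve with apex at 400 Hz: smoothing is symmetric around
  ## the apex, so the peak location is preserved
  tri <- 100 - abs(x - 400) / 5
  m <- monaural_metrics(synthetic_curve(x, tri))
  expect_equal(m$peak_freq, 400, tolerance = 0.02)
  expect_equal(m$baseline_rate, min(tri))
  ## Gaussian bump on a constant baseline: corner at the half-maximum,
  ## x0 + sigma * sqrt(2 log 2)
  g <- 10 + 90 * exp(-(x - 300)^2 / (2 * 150^2))
  m2 <- monaural_metrics(synthetic_curve(x, g))
  half_x <- 300 + 150 * sqrt(2 * log(2))
  expect_lt(abs(m2$corner_freq - half_x), 15)   # 5-point smoothing widens
  expect_equal(m2$baseline_rate, min(g))
  ## flat curve: corner undefined
  m3 <- monaural_metrics(synthetic_curve(x, rep(50, length(x))))
  expect_true(is.na(m3$corner_freq))
})

phase_curve <- function(x, rate, f_m = 300) {
  structure(data.frame(x = x, rate = rate),
            class = c("tuning_curve", "data.frame"),
            kind = "phase_tuning", xlab = "deg", duration_per_point = NA,
            params = NULL, f_m = f_m)
}

test_that("binaural metrics handle cosine and shifted curves exactly", {
  x <- seq(-170, 180, by = 10)
  ## pure cosine: half-peak width 180 degrees, trough opposite the peak.
  ## five-point smoothing on the 10-degree grid scales the cosine amplitude
  ## by the moving-average (Dirichlet) factor but leaves phases, crossings
  ## and the width unchanged
  att <- (1 + 2 * cos(10 * pi / 180) + 2 * cos(20 * pi / 180)) / 5
  y <- 50 + 40 * cos(x * pi / 180)
  m <- binaural_metrics(phase_curve(x, y))
  expect_equal(m$peak_phase, 0)
  expect_equal(m$trough_phase, 180)
  expect_equal(m$half_peak_width, 180, tolerance = 0.02)
  expect_equal(m$peak_rate, 50 + 40 * att, tolerance = 1e-3)
  expect_equal(m$trough_rate, 50 - 40 * att, tolerance = 1e-3)
  ## shifting the curve shifts the phase metrics, rates unchanged
  y2 <- 50 + 40 * cos((x - 30) * pi / 180)
  m2 <- binaural_metrics(phase_curve(x, y2))
  expect_equal(m2$peak_phase, 30)
  expect_equal(m2$trough_phase, -150)
  expect_equal(m2$half_peak_width, m$half_peak_width, tolerance = 0.03)
  expect_equal(m2$peak_rate, m$peak_rate, tolerance = 1e-3)
  ## trough position in ms uses the modulation period
  expect_equal(m2$trough_ms, -150 / 360 / 300 * 1000)
  ## flat curve: phases undefined
  m3 <- binaural_metrics(phase_curve(x, rep(5, length(x))))
  expect_true(is.na(m3$trough_phase))
})

test_that("tuning curves are computed per grid point with matching metrics", {
  pop <- fiber_population()
  prm <- coincidence_params()
  mtf <- compute_rate_mtf(pop, prm, fm_grid = seq(100, 500, by = 100),
                          duration = 3, seed = 52)
  expect_s3_class(mtf, "tuning_curve")
  expect_equal(nrow(mtf), 5)
  expect_true(all(mtf$rate >= 0))
  ## per-point rate equals an independent run_trial with the derived seed
  out3 <- run_trial(stimulus_spec(f_m = 300, duration = 3), pop, prm,
                    "monaural", seed = lsocoin:::derive_seed(52, 101L, 3L))
  expect_equal(mtf$rate[3], output_rate(out3))
  ptc <- compute_phase_tuning(pop, prm, phase_grid = seq(-150, 180, 30),
                              duration = 3, seed = 53)
  expect_equal(nrow(ptc), 12)
  expect_true(all(ptc$rate >= 0))
})
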