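## Brute-force per-bin oracle for the coincidence counter: walks every time
## bin and recounts window membership by exhaustive comparison against all
## input spikes. Only usable for short, small instances.
oracle_counter <- function(exc, inh, duration, dt, params) {
  n_bins <- round(duration / dt)
  eb <- round(exc / dt)
  ib <- round(inh / dt)
  w <- round(params$W / dt)
  tr <- round(params$T / dt)
  d <- round(params$Delta / dt)
  out <- numeric(0)
  last <- -Inf
  for (b in 0:(n_bins - 1)) {
    C <- sum(eb > b - w & eb <= b)
    thr <- params$theta + params$delta * sum(ib > b - d & ib <= b)
    if (C >= thr && b >= last + tr) {
      out <- c(out, b * dt)
      last <- b
    }
  }
  out
}

## Random small coincidence-counter instance on a coarse grid.
random_cc_instance <- function(seed) {
  set.seed(seed)
  dt <- 1e-4
  duration <- 0.05
  n_bins <- round(duration / dt)
  n_exc <- sample(5:120, 1)
  n_inh <- sample(0:40, 1)
  ## duplicate times (coincident spikes on different fibers) are allowed in
  ## the pooled stream; split them over fibers so each fiber is strictly
  ## increasing
  split_by_occurrence <- function(bins) {
    occ <- stats::ave(bins, bins, FUN = seq_along)
    unname(lapply(split(bins * dt, occ), sort))
  }
  exc <- sort(sample(0:(n_bins - 1), n_exc, replace = TRUE))
  inh <- sort(sample(0:(n_bins - 1), n_inh, replace = TRUE))
  params <- coincidence_params(
    theta = sample(1:4, 1),
    W = sample(3:12, 1) * dt,
    T = sample(2:20, 1) * dt,
    Delta = sample(3:20, 1) * dt,
    delta = sample(0:3, 1))
  list(exc = exc * dt, inh = inh * dt,
       exc_trains = split_by_occurrence(exc),
       inh_trains = split_by_occurrence(inh),
       duration = duration, dt = dt, params = params)
}

run_cc <- function(inst) {
  run_coincidence_counter(
    list(exc_trains = inst$exc_trains, inh_trains = inst$inh_trains,
         duration = inst$duration, dt = inst$dt),
    inst$params, dt = inst$dt)
}

## Cumulative intensity of the modulated process, for time-rescaling checks:
## one-period table plus whole-period offsets.
cumulative_intensity <- function(t, rate, vs, f_m) {
  k <- vs_to_kappa(vs)
  P <- 1 / f_m
  tg <- seq(0, P, length.out = 4001)
  lam <- rate * exp(k * cos(2 * pi * f_m * tg)) /
    besselI(k, 0, expon.scaled = TRUE) * exp(-k)
  cum <- c(0, cumsum((lam[-1] + lam[-length(lam)]) / 2 * diff(tg)))
  per_period <- cum[length(cum)]
  frac <- stats::approx(tg, cum, xout = t %% P)$y
  floor(t / P) * per_period + frac
}
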