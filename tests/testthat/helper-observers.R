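# Shared fixtures for the test suite: all built in code, no stored data.

# Deterministic step observer: responds Yes iff delta_t <= threshold_degC.
# Realised as an extreme-gain equal-variance observer; the threshold is
# chosen off the staircase's reachable level lattice so the step is never
# evaluated exactly at its discontinuity.
step_observer <- function(threshold_degC = -0.51) {
  gain <- 1e4
  observer_params(gain = gain, criterion = gain * abs(threshold_degC))
}

# Observer that says Yes to everything / No to everything.
always_yes_observer <- function() observer_params(gain = 1, criterion = -50)
always_no_observer <- function() observer_params(gain = 1e-3, criterion = 50)

# Drive a single staircase branch with a fixed response sequence.
run_responses <- function(cfg, responses) {
  st <- staircase_init(cfg)
  for (r in responses) {
    if (st$finished) break
    st <- staircase_update(st, cfg, r)
  }
  st
}

# Independent brute-force standard-normal quantile: bisection on pnorm.
# Deliberately avoids qnorm so it can serve as the oracle for d'/C.
bisect_qnorm <- function(p, tol = 1e-12) {
  lo <- -10; hi <- 10
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (stats::pnorm(mid) < p) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Sample observer + stimulus pairs whose ~80% point lies inside the
# staircase bounds, for convergence studies.
draw_convergence_observer <- function() {
  repeat {
    g <- stats::runif(1, 1, 3)
    c0 <- stats::runif(1, 0.5, 2)
    thr <- (c0 + stats::qnorm(0.8)) / g
    if (thr > 0.3 && thr < 1.9) {
      return(observer_params(gain = g, criterion = c0))
    }
  }
}
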