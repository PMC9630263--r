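# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: closed forms, brute-force constructions and
# textbook identities only.

G <- 9.81

# Analytic amplitude of the dual-pass Butterworth filter.  The bilinear
# transform maps the analog magnitude response exactly through the
# prewarped frequency W(f) = 2 fs tan(pi f / fs), so a per-pass order-m
# design at (corrected) cutoff fd has dual-pass amplitude
#   1 / (1 + (W(f)/W(fd))^(2 m)).
dualpass_amplitude <- function(f, requested_cutoff, fs, net_order = 4L) {
  m <- net_order / 2
  fd <- requested_cutoff / (sqrt(2) - 1)^(1 / (2 * m))
  W <- function(fr) 2 * fs * tan(pi * fr / fs)
  1 / (1 + (W(f) / W(fd))^(2 * m))
}

# measured steady-state amplitude of a filtered sinusoid (central third,
# away from end transients)
sine_gain <- function(raw, filtered) {
  n <- length(raw)
  idx <- seq.int(floor(n / 3), ceiling(2 * n / 3))
  max(abs(filtered[idx])) / max(abs(raw[idx]))
}

# Brute-force residual-analysis construction, coded independently of
# residual_analysis_cutoff: explicit loop, lm() fit on the upper half of
# the grid, first grid point at or below the zero-frequency intercept.
# The filter itself is the shared primitive under test elsewhere.
oracle_residual_cutoff <- function(series, grid) {
  res <- numeric(length(grid))
  for (i in seq_along(grid)) {
    f <- butterworth_lowpass(series, grid[i])
    res[i] <- sqrt(mean((series$values - f$values)^2))
  }
  k <- length(grid)
  hi <- seq.int(k - floor(k / 2) + 1, k)
  fit <- stats::lm(res[hi] ~ grid[hi])
  icpt <- unname(stats::coef(fit)[1])
  grid[which(res <= icpt)[1]]
}

# closed-form impulse of a half-sine force pulse of amplitude A over
# duration Tdur: integral A sin(pi t / Tdur) dt = 2 A Tdur / pi
halfsine_impulse <- function(A, Tdur) 2 * A * Tdur / pi

# trapezoid rule coded independently (cumulative loop, not vectorised)
oracle_trapz <- function(y, dt) {
  s <- 0
  for (i in seq_len(length(y) - 1)) s <- s + (y[i] + y[i + 1]) / 2 * dt
  s
}

# quick noise-free default dive shared by several files
noisefree_dive <- function(...) {
  simulate_dive(sim_params(noise_sd_pos_m = 0, noise_sd_force_n = 0, ...))
}

# relative error helper
rel_err <- function(est, truth) abs(est - truth) / abs(truth)

# recovery errors of all 14 variables of one processed trial vs its truth
recovery_errors <- function(sim, filter) {
  res <- process_trial(sim$trial, filter = filter)
  vapply(dive_variable_names(),
         function(v) rel_err(res[[v]], sim$truth[[v]]), numeric(1))
}
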