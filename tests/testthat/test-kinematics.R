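# Dive-window detection and displacement / velocity outcomes.

cm_series <- function(x, y, z, rate = 100) {
  uniform_series(cbind(x, y, z), rate = rate)
}

test_that("window detection finds the vertical extrema", {
  n <- 50
  rising <- cm_series(numeric(n), numeric(n), seq(0, 1, length.out = n))
  w <- detect_dive_window(rising)
  expect_equal(c(w$i_start, w$i_end), c(1, n))
  vee <- cm_series(numeric(21), numeric(21), c(seq(1, 0, by = -0.1), seq(0.12, 1.2, length.out = 10)))
  w2 <- detect_dive_window(vee)
  expect_equal(c(w2$i_start, w2$i_end), c(11, 21))
  # falling z only: no rising phase
  falling <- cm_series(numeric(n), numeric(n), seq(1, 0, length.out = n))
  expect_error(detect_dive_window(falling), "no rising phase")
})

test_that("window matches the generator's event times within one sample", {
  sim <- noisefree_dive()
  f <- butterworth_lowpass(sim$trial$cm, 10)
  w <- detect_dive_window(f)
  dt <- 1 / sim$trial$cm$rate
  expect_lte(abs(w$t_start - sim$truth$t_bottom), dt)
  expect_lte(abs(w$t_end - sim$truth$t_apex), dt)
})

test_that("displacements reproduce a worked example and its symmetries", {
  s <- cm_series(c(0.1, 0, 1.36), c(0.05, 0, 0.247), c(0.1, 0, 0.4))
  w <- detect_dive_window(s)
  d <- displacement_components(s, w)
  expect_equal(unname(d), c(0.4, 1.36, 0.247))
  expect_equal(resultant_displacement(d[["VD"]], d[["MLD"]], d[["APD"]]),
               1.439, tolerance = 1e-3)
  # mirror the mediolateral axis: identical MLD
  s2 <- cm_series(-c(0.1, 0, 1.36), c(0.05, 0, 0.247), c(0.1, 0, 0.4))
  expect_equal(displacement_components(s2, detect_dive_window(s2))[["MLD"]],
               d[["MLD"]])
  # zero motion across the window
  s3 <- cm_series(c(0, 0, 0), c(0, 0, 0), c(0.2, 0, 0.5))
  expect_equal(unname(displacement_components(s3, detect_dive_window(s3))[2:3]),
               c(0, 0))
  expect_equal(resultant_displacement(0, 0, 0), 0)
  expect_equal(resultant_displacement(3, 4, 0), 5)
})

test_that("velocities: arithmetic, constant-speed and generator recovery", {
  w <- structure(list(i_start = 1L, i_end = 51L, t_start = 0, t_end = 0.5),
                 class = "dive_window")
  expect_equal(average_velocity(1.5, w), 3.0)
  expect_equal(average_velocity(0, w), 0)
  # straight line at 2 m/s (z rising so the window spans everything)
  t <- seq(0, 0.5, by = 0.01)
  line <- cm_series(2 * t * sqrt(0.5), numeric(length(t)), 2 * t * sqrt(0.5))
  expect_equal(peak_velocity(line, detect_dive_window(line)), 2, tolerance = 1e-9)
  # noise-free synthetic dive: AV and PV against the continuous model
  sim <- noisefree_dive()
  res <- process_trial(sim$trial, filter = filter_config("none"))
  expect_lt(rel_err(res$AV, sim$truth$AV), 5e-3)  # window ends quantised to samples
  expect_lt(rel_err(res$PV, sim$truth$PV), 5e-3)
})

test_that("outcomes are invariant to translation and equivariant to 90-degree rotation", {
  sim <- noisefree_dive()
  cm <- sim$trial$cm
  res <- kinematic_outcomes(cm)
  shifted <- uniform_series(sweep(cm$values, 2, c(3.2, -1.1, 0.7), "+"),
                            rate = cm$rate, t0 = cm$t0)
  res_s <- kinematic_outcomes(shifted)
  for (v in c("VD", "MLD", "APD", "RD", "AV", "PV"))
    expect_equal(res_s[[v]], res[[v]], tolerance = 1e-12, label = v)
  # rotate about z: (x, y) -> (-y, x) swaps ML and AP magnitudes
  rot <- uniform_series(cbind(-cm$values[, 2], cm$values[, 1], cm$values[, 3]),
                        rate = cm$rate, t0 = cm$t0)
  res_r <- kinematic_outcomes(rot)
  expect_equal(res_r$MLD, res$APD, tolerance = 1e-12)
  expect_equal(res_r$APD, res$MLD, tolerance = 1e-12)
  for (v in c("VD", "RD", "AV", "PV"))
    expect_equal(res_r[[v]], res[[v]], tolerance = 1e-12, label = v)
})

test_that("PV >= AV across a session and RD survives measurement noise", {
  trials <- simulate_session(session_config(), seed = 42, compute_truth = TRUE)
  sub <- trials[seq(1, 120, by = 6)]  # 20 trials across subjects/cells
  res <- process_trials(sub, filter = filter_config(cutoff_hz = 10))
  expect_true(all(res$PV >= res$AV))
  # regression: 2 mm position noise + default filtering keeps RD within 2%
  truth_rd <- vapply(sub, function(tr) tr$truth$RD, numeric(1))
  expect_true(all(abs(res$RD - truth_rd) / truth_rd < 0.02))
})
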