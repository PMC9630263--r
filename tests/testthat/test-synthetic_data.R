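# The synthetic dive generator: physical consistency of the continuous
# model, sampling, determinism and the ground-truth channel.

test_that("ballistic flight matches the projectile closed form", {
  sim <- noisefree_dive()
  tr <- sim$trial; tv <- sim$truth
  z <- tr$cm$values[, 3]
  tt <- series_time(tr$cm)
  i_take <- which.min(abs(tt - tv$t_takeoff))
  v0z <- tv$takeoff_velocity[3]
  expect_equal(max(z) - z[i_take], v0z^2 / (2 * G), tolerance = 1e-3)
  # apex time = takeoff + v0z/g
  expect_equal(tv$t_apex - tv$t_takeoff, v0z / G, tolerance = 1e-12)
})

test_that("old rule carries no frontal-step contribution to APD", {
  old <- noisefree_dive(rule = "old")
  new <- noisefree_dive(rule = "new")
  p <- sim_params()
  expect_equal(old$truth$APD, formals(sim_params)$ap_base_m)
  # effect injection: frontal step strictly raises APD, all else equal
  expect_gt(new$truth$APD, old$truth$APD)
  expect_equal(new$truth$APD - old$truth$APD, p$frontal_step_m,
               tolerance = 1e-12)
  # invariant enforced at construction
  expect_error(sim_params(rule = "old", frontal_step_m = 0.2), "old rule")
})

test_that("noise-free pipeline reproduces ground-truth RD to the discretization floor", {
  sim <- noisefree_dive()
  res <- process_trial(sim$trial, filter = filter_config("none"))
  # the sampled z-argmax sits up to half a kinematic sample off the true
  # apex while the CM still moves laterally at ~3 m/s, so the floor is
  # ~v * dt / 2 / RD, not machine precision
  floor_rel <- with(sim$truth, takeoff_velocity[1] * (1 / 400) / 2 / RD)
  expect_lt(rel_err(res$RD, sim$truth$RD), max(1e-5, floor_rel))
})

test_that("non-physical parameter sets are rejected with diagnostics", {
  expect_error(sim_params(countermovement_duration_s = 0.1), "countermovement")
  expect_error(sim_params(flight_apex_height_m = -0.1), "positive")
  expect_error(sim_params(flight_apex_height_m = 1e-6,
                          impulse_duration_s = 0.05), "non-physical")
})

test_that("Newtonian consistency: net vertical force integrates to takeoff momentum", {
  for (rule in c("old", "new")) {
    sim <- noisefree_dive(rule = rule)
    tr <- sim$trial; tv <- sim$truth
    m <- tr$body_mass_kg
    fz <- tr$grf$values[, 3]
    tt <- series_time(tr$grf)
    contact <- tt <= tv$t_takeoff
    dt <- 1 / tr$grf$rate
    imp <- oracle_trapz(fz[contact] - m * G, dt)
    expect_equal(imp / m, tv$takeoff_velocity[3], tolerance = 5e-3)
  }
})

test_that("weight-normalised ground truth is invariant to body mass", {
  a <- noisefree_dive(body_mass_kg = 60)
  b <- noisefree_dive(body_mass_kg = 120)
  for (v in dive_variable_names())
    expect_equal(a$truth[[v]], b$truth[[v]], tolerance = 1e-9,
                 label = paste("truth", v))
  # absolute forces scale with mass
  expect_equal(max(b$trial$grf$values[, 3]) / max(a$trial$grf$values[, 3]),
               2, tolerance = 1e-9)
})

test_that("ground truth satisfies its structural invariants", {
  for (s in list(noisefree_dive(), noisefree_dive(rule = "old", side = "left"))) {
    tv <- s$truth
    expect_gte(tv$RD, max(tv$VD, tv$MLD, tv$APD))
    expect_lte(tv$RD, tv$VD + tv$MLD + tv$APD)
    expect_gte(tv$RPF, max(tv$VPF, tv$MLPF, tv$APPF))
    expect_gte(tv$RI, tv$VI)
    expect_lte(tv$AV, tv$PV)
  }
})

test_that("sessions have the stated design and are seed-deterministic", {
  trials <- simulate_session(session_config(), seed = 7, compute_truth = FALSE)
  expect_length(trials, 120)
  cells <- table(vapply(trials, `[[`, "", "rule"),
                 vapply(trials, `[[`, "", "side"))
  expect_true(all(cells == 30))
  one <- simulate_session(
    session_config(subjects = data.frame(subject_id = "S01",
                                         body_mass_kg = 80,
                                         iplag_score = 4L)),
    seed = 7, compute_truth = FALSE)
  expect_length(one, 20)
  cells1 <- table(vapply(one, `[[`, "", "rule"), vapply(one, `[[`, "", "side"))
  expect_true(all(cells1 == 5))
  # determinism: identical object trees for equal seeds
  again <- simulate_session(
    session_config(subjects = data.frame(subject_id = "S01",
                                         body_mass_kg = 80,
                                         iplag_score = 4L)),
    seed = 7, compute_truth = FALSE)
  expect_identical(one, again)
  expect_false(identical(
    one, simulate_session(session_config(subjects = data.frame(
      subject_id = "S01", body_mass_kg = 80, iplag_score = 4L)),
      seed = 8, compute_truth = FALSE)))
})

test_that("the two channels are sampled on distinct clocks", {
  sim <- noisefree_dive()
  tk <- series_time(sim$trial$cm)
  tf <- series_time(sim$trial$grf)
  expect_equal(sim$trial$cm$rate, 400)
  expect_equal(sim$trial$grf$rate, 2000)
  expect_length(intersect(tk, tf), 0)
})
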