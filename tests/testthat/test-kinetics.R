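# Impulse-phase detection and weight-normalised force / impulse outcomes.

grf_series <- function(fx, fy, fz, rate = 2000) {
  uniform_series(cbind(fx, fy, fz), rate = rate)
}

test_that("impulse phase brackets a rectangular pulse and rejects degenerate traces", {
  m <- 80
  rate <- 2000
  t <- (0:round(1.5 * rate)) / rate
  fz <- ifelse(t >= 1 & t <= 1.2, 2 * m * G, 0)
  g <- grf_series(numeric(length(t)), numeric(length(t)), fz, rate)
  ph <- detect_impulse_phase(g, m)
  expect_equal(ph$t_on, 1, tolerance = 2 / rate)
  expect_equal(ph$t_off, 1.2, tolerance = 2 / rate)
  pf <- peak_forces(g, ph, m)
  expect_equal(unname(pf[c("VPF", "RPF")]), c(2, 2), tolerance = 1e-12)
  im <- impulses(g, ph, m)
  expect_equal(unname(im[["VI"]]), 2 * 0.2, tolerance = 2e-2)
  # degenerate traces
  zeros <- grf_series(numeric(100), numeric(100), numeric(100))
  expect_error(detect_impulse_phase(zeros, m), "no impulse detected")
  quiet <- grf_series(numeric(100), numeric(100), rep(m * G, 100))
  expect_error(detect_impulse_phase(quiet, m), "no impulse detected")
  # force never returns to baseline: no takeoff
  stuck <- grf_series(numeric(200), numeric(200),
                      c(rep(m * G, 100), rep(2 * m * G, 100)))
  expect_error(detect_impulse_phase(stuck, m), "no takeoff")
})

test_that("weight normalisation identities hold", {
  m <- 75
  n <- 200
  standing <- grf_series(numeric(n), numeric(n), rep(m * G, n))
  ph <- structure(list(i_on = 1L, i_off = n, t_on = 0, t_off = (n - 1) / 2000),
                  class = "impulse_phase")
  pf <- peak_forces(standing, ph, m)
  expect_equal(unname(pf[c("VPF", "RPF")]), c(1, 1), tolerance = 1e-12)
  # single-sample spike at 2 BW
  spike <- standing
  spike$values[100, 3] <- 2 * m * G
  expect_equal(unname(peak_forces(spike, ph, m)[["VPF"]]), 2, tolerance = 1e-12)
  # RI == VI when horizontal axes are identically zero
  im <- impulses(standing, ph, m)
  expect_equal(im[["RI"]], im[["VI"]], tolerance = 1e-12)
})

test_that("trapezoidal impulse matches the half-sine closed form with O(dt^2) error", {
  m <- 80
  A <- 1.6 * m * G
  Tdur <- 0.3
  exact <- halfsine_impulse(A, Tdur) / (m * G)
  vi_at <- function(rate) {
    t <- (0:round(Tdur * rate)) / rate
    fz <- A * sin(pi * t / Tdur)
    g <- grf_series(numeric(length(t)), numeric(length(t)), fz, rate)
    ph <- structure(list(i_on = 1L, i_off = length(t), t_on = 0, t_off = Tdur),
                    class = "impulse_phase")
    impulses(g, ph, m)[["VI"]]
  }
  err2000 <- abs(vi_at(2000) - exact) / exact
  err1000 <- abs(vi_at(1000) - exact) / exact
  expect_lt(err2000, 1e-4)            # < 0.01 % at 2000 Hz
  expect_gt(err1000 / err2000, 3)     # halving the rate ~quadruples the error
  expect_lt(err1000 / err2000, 5)
})

test_that("synthetic trial: takeoff timing and peak force recover the ground truth", {
  sim <- noisefree_dive()
  tr <- sim$trial
  ph <- detect_impulse_phase(tr$grf, tr$body_mass_kg)
  # the 10 N foot-off threshold fires early by threshold / |dF/dt| with the
  # *local* slope at takeoff; allow that deterministic bias plus one sample
  fz <- tr$grf$values[, 3]
  local_slope <- abs(fz[ph$i_off] - fz[ph$i_off - 4L]) / 4 * tr$grf$rate
  expect_lte(abs(ph$t_off - sim$truth$t_takeoff),
             10 / local_slope + 1 / tr$grf$rate)
  expect_lte(abs(ph$t_on - sim$truth$t_impulse_on), 2 / tr$grf$rate)
  pf <- peak_forces(tr$grf, ph, tr$body_mass_kg)
  expect_lt(rel_err(pf[["VPF"]], sim$truth$VPF), 5e-3)
  # Newtonian cross-check over the detected phase: normalised net impulse
  # equals the velocity gained between onset and takeoff, over g
  im <- impulses(tr$grf, ph, tr$body_mass_kg)
  dv <- sim$truth$takeoff_velocity[3] - sim$truth$onset_velocity[3]
  expect_equal(im[["VI"]] - (ph$t_off - ph$t_on), dv / G, tolerance = 5e-3)
})

test_that("outcomes are invariant to common force/mass rescaling", {
  sim <- noisefree_dive()
  tr <- sim$trial
  ph <- detect_impulse_phase(tr$grf, tr$body_mass_kg)
  base <- c(peak_forces(tr$grf, ph, tr$body_mass_kg),
            impulses(tr$grf, ph, tr$body_mass_kg))
  # same phase for both: the absolute 10 N foot-off threshold is (by
  # design) not scale-invariant, the weight normalisation is
  grf2 <- uniform_series(3 * tr$grf$values, rate = tr$grf$rate, t0 = tr$grf$t0)
  scaled <- c(peak_forces(grf2, ph, 3 * tr$body_mass_kg),
              impulses(grf2, ph, 3 * tr$body_mass_kg))
  expect_equal(scaled, base, tolerance = 1e-12)
})
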