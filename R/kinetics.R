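# Impulse-phase detection on the force plate and the weight-normalised
# peak-force and impulse outcomes.
#
# The push-off phase starts at the last upward crossing of
# onset_factor * body weight before the vertical-force peak (standard
# jump-analysis onset after the unloading dip) and ends at foot-off, the
# first sample after the peak with vertical force below the contact
# threshold.  Forces are analysed on their native clock; peaks and
# trapezoidal impulses are normalised by body weight m*g with g = 9.81.

#' Detect the push-off impulse phase
#'
#' @param grf a 3-axis [uniform_series()] of ground-reaction force
#'   (fx, fy, fz), filtered.
#' @param body_mass_kg body mass in kg.
#' @param onset_factor onset threshold as a multiple of body weight
#'   (default 1.05).
#' @param contact_threshold_n foot-off threshold in newtons (default 10).
#' @return an `impulse_phase` list with `i_on`, `i_off`, `t_on`, `t_off`.
#' @export
detect_impulse_phase <- function(grf, body_mass_kg, onset_factor = 1.05,
                                 contact_threshold_n = 10) {
  stopifnot(inherits(grf, "uniform_series"), ncol(grf$values) == 3L,
            body_mass_kg > 0)
  fz <- grf$values[, 3L]
  onset_level <- onset_factor * body_mass_kg * GRAVITY
  if (max(fz) <= onset_level)
    stop(sprintf("detect_impulse_phase: no impulse detected (vertical force never exceeds %.1f N)",
                 onset_level))
  i_pk <- which.max(fz)
  below <- which(fz[seq_len(i_pk)] < onset_level)
  i_on <- if (length(below) == 0L) 1L else max(below) + 1L
  after <- which(fz[i_pk:length(fz)] < contact_threshold_n)
  if (length(after) == 0L)
    stop(sprintf("detect_impulse_phase: no takeoff detected (vertical force never falls below %.1f N after the peak)",
                 contact_threshold_n))
  i_off <- i_pk + after[1L] - 1L
  tt <- series_time(grf)
  structure(list(i_on = i_on, i_off = i_off,
                 t_on = tt[i_on], t_off = tt[i_off]),
            class = "impulse_phase")
}

#' Weight-normalised peak forces
#'
#' Per axis, the maximum absolute force within the impulse phase divided by
#' body weight; the resultant peak (RPF) is the maximum of the sample-wise
#' Euclidean norm of the force vector (norm-then-max, the physical GRF
#' magnitude), also weight-normalised.
#'
#' @param grf a 3-axis [uniform_series()] of force.
#' @param phase an `impulse_phase` from [detect_impulse_phase()].
#' @param body_mass_kg body mass in kg.
#' @return named numeric vector `c(VPF, MLPF, APPF, RPF)` in xBW.
#' @export
peak_forces <- function(grf, phase, body_mass_kg) {
  stopifnot(inherits(grf, "uniform_series"), inherits(phase, "impulse_phase"),
            body_mass_kg > 0)
  mg <- body_mass_kg * GRAVITY
  f <- grf$values[phase$i_on:phase$i_off, , drop = FALSE]
  res <- sqrt(rowSums(f^2))
  c(VPF = max(abs(f[, 3L])) / mg,
    MLPF = max(abs(f[, 1L])) / mg,
    APPF = max(abs(f[, 2L])) / mg,
    RPF = max(res) / mg)
}

#' Weight-normalised impulses
#'
#' Per axis, the trapezoidal integral of the absolute force over the
#' impulse phase divided by body weight (units xBW.s); the resultant
#' impulse (RI) integrates the sample-wise force-vector magnitude
#' (norm-then-integrate).
#'
#' @inheritParams peak_forces
#' @param signed logical; integrate signed rather than absolute per-axis
#'   force (default `FALSE`: absolute, so dive direction cannot flip signs).
#' @return named numeric vector `c(VI, MLI, API, RI)` in xBW.s.
#' @export
impulses <- function(grf, phase, body_mass_kg, signed = FALSE) {
  stopifnot(inherits(grf, "uniform_series"), inherits(phase, "impulse_phase"),
            body_mass_kg > 0)
  mg <- body_mass_kg * GRAVITY
  dt <- 1 / grf$rate
  f <- grf$values[phase$i_on:phase$i_off, , drop = FALSE]
  fa <- if (signed) f else abs(f)
  res <- sqrt(rowSums(f^2))
  c(VI = trapz_uniform(fa[, 3L], dt) / mg,
    MLI = trapz_uniform(fa[, 1L], dt) / mg,
    API = trapz_uniform(fa[, 2L], dt) / mg,
    RI = trapz_uniform(res, dt) / mg)
}

#' All kinetic outcomes of one trial
#'
#' Convenience wrapper: impulse-phase detection plus the eight
#' weight-normalised force/impulse variables.
#'
#' @inheritParams detect_impulse_phase
#' @return named list with `VPF`, `MLPF`, `APPF`, `RPF`, `VI`, `MLI`,
#'   `API`, `RI` and the detected `phase`.
#' @export
kinetic_outcomes <- function(grf, body_mass_kg, onset_factor = 1.05,
                             contact_threshold_n = 10) {
  phase <- detect_impulse_phase(grf, body_mass_kg, onset_factor,
                                contact_threshold_n)
  pf <- peak_forces(grf, phase, body_mass_kg)
  im <- impulses(grf, phase, body_mass_kg)
  c(as.list(pf), as.list(im), list(phase = phase))
}
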