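# Mechanistic synthetic dive generator.
#
# A goalkeeper's penalty dive is modelled as a C1-continuous piecewise
# trajectory of the centre of mass (CM): quiet stance -> countermovement
# (vertical unloading dip) -> push-off impulse (lateral, forward and upward
# acceleration) -> ballistic flight to the reach target.  During ground
# contact the ground-reaction force is exactly F(t) = m * (a(t) + g * ez),
# reaching zero at takeoff; after takeoff F = 0 and the CM is ballistic.
# Kinematic and force channels are sampled on independent clocks and
# corrupted with white Gaussian noise.  All outcome variables are computed
# analytically (or by adaptive quadrature / optimisation on the continuous
# model) before sampling, providing an exact ground-truth channel for
# recovery tests.

GRAVITY <- 9.81  # m/s^2, fixed

#' Parameters of one synthetic dive
#'
#' Defaults describe a realistic laboratory penalty dive: an adult
#' goalkeeper (81.6 kg) diving toward a high corner target, with a ~1.4 m
#' mediolateral CM reach, a 0.25 m countermovement dip and a 0.35 s
#' push-off.  Under the new feet-positioning rule the goalkeeper projects a
#' foot forward, adding `frontal_step_m` of anteroposterior CM motion on top
#' of the intrinsic `ap_base_m`; under the old rule `frontal_step_m` must be
#' 0 (lateral-only impulse).
#'
#' @param body_mass_kg body mass in kg.
#' @param rule feet-positioning rule, `"old"` or `"new"`.
#' @param side dive side, `"left"` or `"right"` (mediolateral samples are
#'   signed toward the dive side; outcome variables use magnitudes).
#' @param stance_duration_s quiet stance before movement onset, s.
#' @param countermovement_duration_s duration of the unloading dip, s.
#' @param countermovement_depth_m vertical CM drop during the dip, m.
#' @param impulse_duration_s push-off duration (bottom to takeoff), s.
#' @param flight_apex_height_m ballistic CM rise above takeoff height, m.
#' @param lateral_reach_m mediolateral CM displacement from countermovement
#'   bottom to flight apex, m.
#' @param ap_base_m intrinsic anteroposterior CM displacement over the same
#'   window, m.
#' @param frontal_step_m additional anteroposterior displacement from the
#'   frontal foot projection allowed by the new rule, m; must be 0 under the
#'   old rule.
#' @param post_apex_s recorded flight time beyond the apex, s.
#' @param stance_height_m CM height during quiet stance, m.
#' @param kin_rate_hz motion-capture sampling rate, Hz (default 400).
#' @param force_rate_hz force-plate sampling rate, Hz (default 2000).
#' @param noise_sd_pos_m SD of additive white Gaussian position noise, m.
#' @param noise_sd_force_n SD of additive white Gaussian force noise, N.
#' @param seed optional integer seed for the noise draws.
#' @return a validated `sim_params` object.
#' @export
sim_params <- function(body_mass_kg = 81.6,
                       rule = c("new", "old"),
                       side = c("right", "left"),
                       stance_duration_s = 0.50,
                       countermovement_duration_s = 0.40,
                       countermovement_depth_m = 0.25,
                       impulse_duration_s = 0.35,
                       flight_apex_height_m = 0.10,
                       lateral_reach_m = 1.40,
                       ap_base_m = 0.25,
                       frontal_step_m = if (match.arg(rule) == "new") 0.25 else 0,
                       post_apex_s = 0.20,
                       stance_height_m = 1.00,
                       kin_rate_hz = 400,
                       force_rate_hz = 2000,
                       noise_sd_pos_m = 0.002,
                       noise_sd_force_n = 5,
                       seed = NULL) {
  rule <- match.arg(rule)
  side <- match.arg(side)
  p <- list(body_mass_kg = body_mass_kg, rule = rule, side = side,
            stance_duration_s = stance_duration_s,
            countermovement_duration_s = countermovement_duration_s,
            countermovement_depth_m = countermovement_depth_m,
            impulse_duration_s = impulse_duration_s,
            flight_apex_height_m = flight_apex_height_m,
            lateral_reach_m = lateral_reach_m,
            ap_base_m = ap_base_m,
            frontal_step_m = frontal_step_m,
            post_apex_s = post_apex_s,
            stance_height_m = stance_height_m,
            kin_rate_hz = kin_rate_hz, force_rate_hz = force_rate_hz,
            noise_sd_pos_m = noise_sd_pos_m,
            noise_sd_force_n = noise_sd_force_n,
            seed = seed)
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  num_pos <- c("body_mass_kg", "stance_duration_s", "countermovement_duration_s",
               "countermovement_depth_m", "impulse_duration_s",
               "flight_apex_height_m", "lateral_reach_m", "stance_height_m",
               "kin_rate_hz", "force_rate_hz")
  for (f in num_pos)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) || p[[f]] <= 0)
      stop(sprintf("sim_params: '%s' must be a positive finite scalar (got %s)",
                   f, format(p[[f]])))
  num_nonneg <- c("ap_base_m", "frontal_step_m", "post_apex_s",
                  "noise_sd_pos_m", "noise_sd_force_n")
  for (f in num_nonneg)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) || p[[f]] < 0)
      stop(sprintf("sim_params: '%s' must be a nonnegative finite scalar", f))
  if (p$rule == "old" && p$frontal_step_m > 0)
    stop("sim_params: frontal_step_m must be 0 under the old rule (lateral-only impulse)")
  # dynamic feasibility of the continuous model
  g <- GRAVITY
  alpha0 <- (p$countermovement_depth_m / 2) * (pi / p$countermovement_duration_s)^2
  if (alpha0 >= g)
    stop(sprintf(paste("sim_params: countermovement too violent (peak unloading %.2f m/s^2",
                       ">= g); vertical force would become negative -- deepen or slow the dip"),
                 alpha0))
  co <- pushoff_cubic(alpha0, p$impulse_duration_s,
                      sqrt(2 * g * p$flight_apex_height_m))
  u <- seq(0, p$impulse_duration_s, length.out = 257L)
  vz <- alpha0 * u + co[1L] * u^2 + co[2L] * u^3
  if (min(vz) < -1e-9)
    stop("sim_params: non-physical parameter set -- CM would descend during the push-off; lengthen impulse_duration_s or reduce flight_apex_height_m")
  az <- alpha0 + 2 * co[1L] * u + 3 * co[2L] * u^2
  if (min(az) < -g - 1e-9)
    stop("sim_params: non-physical parameter set -- vertical force would become negative during the push-off")
  dz_push <- alpha0 * p$impulse_duration_s^2 / 2 +
    co[1L] * p$impulse_duration_s^3 / 3 + co[2L] * p$impulse_duration_s^4 / 4
  if (dz_push + p$flight_apex_height_m <= p$countermovement_depth_m + 1e-9)
    stop("sim_params: non-physical parameter set -- flight apex does not rise above stance height (impulse too short to reach target)")
  invisible(p)
}

# cubic vertical-velocity coefficients (c2, c3) on the push-off:
# v(0) = 0, v'(0) = alpha0, v(Tp) = v0z, v'(Tp) = -g
pushoff_cubic <- function(alpha0, Tp, v0z) {
  A <- rbind(c(Tp^2, Tp^3), c(2 * Tp, 3 * Tp^2))
  solve(A, c(v0z - alpha0 * Tp, -GRAVITY - alpha0))
}

# smoothstep and its integral / derivative (horizontal velocity shape)
ss_f  <- function(s) 3 * s^2 - 2 * s^3
ss_i  <- function(s) s^3 - s^4 / 2
ss_d  <- function(s) 6 * s - 6 * s^2

# Build the continuous dive model: closed-form position / velocity /
# acceleration of the CM as vectorised functions of absolute time, plus the
# event times.  All horizontal motion develops over countermovement +
# push-off with a smoothstep velocity profile ending at the takeoff
# velocity; the vertical push-off velocity is the constrained cubic.
make_dive_model <- function(p) {
  g <- GRAVITY
  Ts <- p$stance_duration_s; Tc <- p$countermovement_duration_s
  d <- p$countermovement_depth_m; Tp <- p$impulse_duration_s
  z0 <- p$stance_height_m
  v0z <- sqrt(2 * g * p$flight_apex_height_m)
  alpha0 <- (d / 2) * (pi / Tc)^2
  cc <- pushoff_cubic(alpha0, Tp, v0z)
  c2 <- cc[1L]; c3 <- cc[2L]
  t1 <- Ts + Tc            # countermovement bottom = push-off onset
  t2 <- t1 + Tp            # takeoff
  t_ap <- v0z / g
  t_apex <- t2 + t_ap
  t_end <- t_apex + p$post_apex_s
  Th <- Tc + Tp            # horizontal build-up duration
  sb <- Tc / Th
  # takeoff horizontal velocities from the window reach targets
  denom <- Th * (0.5 - ss_i(sb)) + t_ap
  v0x <- p$lateral_reach_m / denom
  ap_total <- p$ap_base_m + p$frontal_step_m
  v0y <- ap_total / denom
  z_bottom <- z0 - d
  dz_push <- alpha0 * Tp^2 / 2 + c2 * Tp^3 / 3 + c3 * Tp^4 / 4
  z_take <- z_bottom + dz_push
  x_take <- v0x * Th / 2
  y_take <- v0y * Th / 2

  horiz <- function(t, v0, deriv) {
    # horizontal kinematics (per axis, amplitude v0) vs absolute time
    u <- t - Ts
    out <- numeric(length(t))
    build <- t >= Ts & t < t2
    fly <- t >= t2
    s <- u[build] / Th
    if (deriv == 0L) {
      out[build] <- v0 * Th * ss_i(s)
      out[fly] <- v0 * Th / 2 + v0 * (t[fly] - t2)
    } else if (deriv == 1L) {
      out[build] <- v0 * ss_f(s)
      out[fly] <- v0
    } else {
      out[build] <- v0 * ss_d(s) / Th
    }
    out
  }
  vert <- function(t, deriv) {
    out <- numeric(length(t))
    cm <- t >= Ts & t < t1
    pu <- t >= t1 & t < t2
    fly <- t >= t2
    u <- t[cm] - Ts
    if (deriv == 0L) {
      out[t < Ts] <- z0
      out[cm] <- z0 - (d / 2) * (1 - cos(pi * u / Tc))
      up <- t[pu] - t1
      out[pu] <- z_bottom + alpha0 * up^2 / 2 + c2 * up^3 / 3 + c3 * up^4 / 4
      uf <- t[fly] - t2
      out[fly] <- z_take + v0z * uf - g * uf^2 / 2
    } else if (deriv == 1L) {
      out[cm] <- -(d * pi / (2 * Tc)) * sin(pi * u / Tc)
      up <- t[pu] - t1
      out[pu] <- alpha0 * up + c2 * up^2 + c3 * up^3
      out[fly] <- v0z - g * (t[fly] - t2)
    } else {
      out[cm] <- -alpha0 * cos(pi * u / Tc)
      up <- t[pu] - t1
      out[pu] <- alpha0 + 2 * c2 * up + 3 * c3 * up^2
      out[fly] <- -g
    }
    out
  }
  pos <- function(t) cbind(x = horiz(t, v0x, 0L), y = horiz(t, v0y, 0L),
                           z = vert(t, 0L))
  vel <- function(t) cbind(x = horiz(t, v0x, 1L), y = horiz(t, v0y, 1L),
                           z = vert(t, 1L))
  acc <- function(t) cbind(x = horiz(t, v0x, 2L), y = horiz(t, v0y, 2L),
                           z = vert(t, 2L))
  force <- function(t) {
    a <- acc(t)
    contact <- t < t2
    f <- p$body_mass_kg * (a + cbind(0, 0, rep(g, length(t))))
    f[!contact, ] <- 0
    colnames(f) <- c("fx", "fy", "fz")
    f
  }
  list(p = p, alpha0 = alpha0, c2 = c2, c3 = c3,
       v0x = v0x, v0y = v0y, v0z = v0z,
       t1 = t1, t2 = t2, t_ap = t_ap, t_apex = t_apex, t_end = t_end,
       Th = Th, z_bottom = z_bottom, z_take = z_take,
       dz_push = dz_push, ap_total = ap_total,
       pos = pos, vel = vel, acc = acc, force = force)
}

# continuous-time impulse-phase onset: last upward crossing of
# onset_factor * body weight before the force peak (standard jump-analysis
# onset); takeoff ends the phase with F exactly 0.
model_impulse_onset <- function(m, onset_factor = 1.05) {
  g <- GRAVITY
  thr <- (onset_factor - 1) * g        # required vertical CM acceleration
  p <- m$p
  Tc <- p$countermovement_duration_s
  if (m$alpha0 > thr) {
    # crossing happens on the rising half of the countermovement
    u <- (Tc / pi) * acos(-thr / m$alpha0)
    p$stance_duration_s + u
  } else {
    # crossing happens during the push-off: solve the quadratic acceleration
    f <- function(u) m$alpha0 + 2 * m$c2 * u + 3 * m$c3 * u^2 - thr
    if (f(0) >= 0) return(m$t1)
    ur <- stats::uniroot(f, c(0, p$impulse_duration_s), tol = 1e-12)$root
    m$t1 + ur
  }
}

# maximum of a continuous scalar function on [lo, hi]: dense grid plus local
# refinement (robust to multimodality of the model curves)
cont_max <- function(f, lo, hi, n_grid = 512L) {
  tt <- seq(lo, hi, length.out = n_grid)
  y <- f(tt)
  i <- which.max(y)
  a <- tt[max(1L, i - 1L)]; b <- tt[min(n_grid, i + 1L)]
  if (a == b) return(y[i])
  o <- stats::optimize(f, c(a, b), maximum = TRUE, tol = 1e-12)
  max(y[i], o$objective)
}

# Exact outcome variables from the continuous generating model (pre-noise,
# pre-sampling).  Resultant peak force and impulse need quadrature /
# optimisation; everything else is closed form.
dive_ground_truth <- function(m, onset_factor = 1.05) {
  g <- GRAVITY
  p <- m$p
  VD <- m$dz_push + p$flight_apex_height_m
  MLD <- p$lateral_reach_m
  APD <- m$ap_total
  RD <- sqrt(VD^2 + MLD^2 + APD^2)
  Tw <- p$impulse_duration_s + m$t_ap
  AV <- RD / Tw
  speed <- function(t) sqrt(rowSums(m$vel(t)^2))
  PV <- max(cont_max(speed, m$t1, m$t2),
            sqrt(m$v0x^2 + m$v0y^2 + m$v0z^2))  # flight speed peaks at takeoff
  t_on <- model_impulse_onset(m, onset_factor)
  mg <- p$body_mass_kg * g
  fcomp <- function(t, j) abs(m$force(t)[, j])
  VPF <- cont_max(function(t) fcomp(t, 3L), t_on, m$t2) / mg
  MLPF <- cont_max(function(t) fcomp(t, 1L), t_on, m$t2) / mg
  APPF <- cont_max(function(t) fcomp(t, 2L), t_on, m$t2) / mg
  fres <- function(t) sqrt(rowSums(m$force(t)^2))
  RPF <- cont_max(fres, t_on, m$t2) / mg
  # per-axis impulses: |F| integrates in closed form because every component
  # is nonnegative during the phase (velocity differences); resultant needs
  # quadrature
  v_on <- m$vel(t_on)
  VI <- ((m$v0z - v_on[3L]) + g * (m$t2 - t_on)) / g
  MLI <- (m$v0x - v_on[1L]) / g
  API <- (m$v0y - v_on[2L]) / g
  RI <- stats::integrate(fres, t_on, m$t2, rel.tol = 1e-10,
                         subdivisions = 2000L)$value / mg
  structure(list(VD = VD, MLD = MLD, APD = APD, RD = RD, AV = AV, PV = PV,
                 VPF = VPF, MLPF = MLPF, APPF = APPF, RPF = RPF,
                 VI = VI, MLI = MLI, API = API, RI = RI,
                 t_bottom = m$t1, t_takeoff = m$t2, t_apex = m$t_apex,
                 t_impulse_on = t_on,
                 takeoff_velocity = c(m$v0x, m$v0y, m$v0z),
                 onset_velocity = as.numeric(v_on)),
            class = "dive_truth")
}

# evaluate an expression with a temporary RNG state
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' One dive trial: trajectories, forces and metadata
#'
#' @param trial_id,subject_id identifiers.
#' @param body_mass_kg body mass, kg.
#' @param rule `"old"` or `"new"`; @param side `"left"` or `"right"`.
#' @param iplag_score lower-limb lateral-preference score, integer 1-5.
#' @param quality `"ok"` or `"discarded"` (capture problems upstream).
#' @param cm CM trajectory, a [uniform_series()] in metres.
#' @param grf ground-reaction force, a [uniform_series()] in newtons.
#' @param truth optional `dive_truth` (synthetic trials only).
#' @return a `trial_record`.
#' @export
trial_record <- function(trial_id, subject_id, body_mass_kg, rule, side,
                         iplag_score, quality = "ok", cm, grf, truth = NULL) {
  stopifnot(body_mass_kg > 0, rule %in% c("old", "new"),
            side %in% c("left", "right"), quality %in% c("ok", "discarded"))
  if (quality == "ok" && (length(cm) == 0L || length(grf) == 0L))
    stop("trial_record: both channels must be non-empty when quality = 'ok'")
  structure(list(trial_id = as.character(trial_id),
                 subject_id = as.character(subject_id),
                 body_mass_kg = body_mass_kg, rule = rule, side = side,
                 iplag_score = as.integer(iplag_score), quality = quality,
                 cm = cm, grf = grf, truth = truth),
            class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record %s> subject %s, %.1f kg, rule %s, side %s, IPLAG %d, %s\n",
              x$trial_id, x$subject_id, x$body_mass_kg, x$rule, x$side,
              x$iplag_score, x$quality))
  invisible(x)
}

#' Simulate one synthetic dive
#'
#' Samples the continuous dive model on the kinematic and force-plate
#' clocks, adds i.i.d. Gaussian measurement noise per channel, and returns
#' the sampled trial together with the exact ground-truth outcome variables
#' computed from the continuous model (never from the samples, so any
#' discrepancy downstream is attributable to the pipeline).
#'
#' The two clocks are independent: the force clock is offset by half a
#' force sample so the channels share no timestamps, as with real
#' instrumentation.
#'
#' @param params a [sim_params()] object.
#' @param trial_id,subject_id identifiers stored in the trial record.
#' @param iplag_score lateral-preference score stored in the record.
#' @param quality `"ok"` (default) or `"discarded"`.
#' @return a list with elements `trial` (a [trial_record()]) and `truth`
#'   (the exact `dive_truth`).
#' @examples
#' sd <- simulate_dive(sim_params(noise_sd_pos_m = 0, noise_sd_force_n = 0))
#' sd$truth$RD
#' @export
simulate_dive <- function(params, trial_id = "T01", subject_id = "S01",
                          iplag_score = 4L, quality = "ok") {
  stopifnot(inherits(params, "sim_params"))
  m <- make_dive_model(params)
  truth <- dive_ground_truth(m)
  n_kin <- floor(m$t_end * params$kin_rate_hz) + 1L
  t_kin <- (seq_len(n_kin) - 1L) / params$kin_rate_hz
  f_t0 <- 0.5 / params$force_rate_hz
  n_frc <- floor((m$t_end - f_t0) * params$force_rate_hz) + 1L
  t_frc <- f_t0 + (seq_len(n_frc) - 1L) / params$force_rate_hz
  pos <- m$pos(t_kin)
  frc <- m$force(t_frc)
  sgn <- if (params$side == "left") -1 else 1
  pos[, 1L] <- sgn * pos[, 1L]
  frc[, 1L] <- sgn * frc[, 1L]
  with_seed(params$seed, {
    if (params$noise_sd_pos_m > 0)
      pos <- pos + matrix(stats::rnorm(length(pos), 0, params$noise_sd_pos_m),
                          nrow = nrow(pos))
    if (params$noise_sd_force_n > 0)
      frc <- frc + matrix(stats::rnorm(length(frc), 0, params$noise_sd_force_n),
                          nrow = nrow(frc))
  })
  colnames(pos) <- c("x", "y", "z")
  colnames(frc) <- c("fx", "fy", "fz")
  tr <- trial_record(trial_id, subject_id, params$body_mass_kg, params$rule,
                     params$side, iplag_score, quality,
                     cm = uniform_series(pos, rate = params$kin_rate_hz, t0 = 0),
                     grf = uniform_series(frc, rate = params$force_rate_hz,
                                          t0 = f_t0),
                     truth = truth)
  list(trial = tr, truth = truth)
}

#' Configuration of a simulated collection session
#'
#' Defaults emulate the experimental design of a laboratory penalty-dive
#' study: 6 goalkeepers, 20 dives each (5 per rule-by-side cell, order
#' randomised), one left-footed subject among six, trial-to-trial and
#' subject-to-subject lognormal variability of the dive parameters, and the
#' new-rule frontal step as the injected rule effect (set
#' `frontal_step_m = 0` for a null world with no rule effect).
#'
#' @param subjects data.frame with columns `subject_id`, `body_mass_kg`,
#'   `iplag_score`.
#' @param n_per_cell trials per rule-by-side cell per subject (default 5).
#' @param base named list of overrides for the baseline [sim_params()]
#'   (fields other than rule, side, mass, frontal step, noise, seed).
#' @param frontal_step_m anteroposterior frontal-step displacement injected
#'   in new-rule trials, m.
#' @param subject_cv,trial_cv coefficients of variation of the lognormal
#'   subject-level and trial-level jitter applied to the dive-shape
#'   parameters.
#' @param jitter_fields parameter names receiving the jitter.
#' @param noise_sd_pos_m,noise_sd_force_n measurement noise SDs.
#' @param discard_rate probability that a trial is flagged `"discarded"`
#'   (capture failure), default 0.
#' @return a `session_config` list.
#' @export
session_config <- function(subjects = data.frame(
                             subject_id = sprintf("S%02d", 1:6),
                             body_mass_kg = c(68, 72, 79, 84, 90, 97),
                             iplag_score = c(2L, 4L, 5L, 4L, 5L, 4L)),
                           n_per_cell = 5L,
                           base = list(),
                           frontal_step_m = 0.25,
                           subject_cv = 0.06,
                           trial_cv = 0.05,
                           jitter_fields = c("countermovement_depth_m",
                                             "flight_apex_height_m",
                                             "lateral_reach_m",
                                             "ap_base_m",
                                             "impulse_duration_s"),
                           noise_sd_pos_m = 0.002,
                           noise_sd_force_n = 5,
                           discard_rate = 0) {
  stopifnot(nrow(subjects) >= 1L,
            all(c("subject_id", "body_mass_kg", "iplag_score") %in% names(subjects)),
            all(subjects$body_mass_kg > 0),
            all(subjects$iplag_score %in% 1:5),
            n_per_cell >= 1L, frontal_step_m >= 0,
            subject_cv >= 0, trial_cv >= 0,
            discard_rate >= 0, discard_rate < 1)
  structure(list(subjects = subjects, n_per_cell = as.integer(n_per_cell),
                 base = base, frontal_step_m = frontal_step_m,
                 subject_cv = subject_cv, trial_cv = trial_cv,
                 jitter_fields = jitter_fields,
                 noise_sd_pos_m = noise_sd_pos_m,
                 noise_sd_force_n = noise_sd_force_n,
                 discard_rate = discard_rate),
            class = "session_config")
}

#' Simulate a full collection session
#'
#' Per subject, `4 * n_per_cell` trials (old/new rule crossed with
#' left/right side) in randomised order.  All randomness -- parameter
#' jitter, trial order, measurement noise, discard flags -- flows from the
#' single `seed`; equal seeds give identical output.
#'
#' @param cfg a [session_config()].
#' @param seed integer seed.
#' @param compute_truth logical; keep the (moderately expensive) exact
#'   ground-truth channel on each record.  Set `FALSE` for large replicate
#'   studies where only the sampled signals are needed.
#' @return list of [trial_record()]s (each with `$truth` unless disabled).
#' @export
simulate_session <- function(cfg = session_config(), seed = 1L,
                             compute_truth = TRUE) {
  stopifnot(inherits(cfg, "session_config"))
  with_seed(seed, {
    trials <- list()
    for (si in seq_len(nrow(cfg$subjects))) {
      sub <- cfg$subjects[si, ]
      smult <- stats::setNames(exp(stats::rnorm(length(cfg$jitter_fields), 0,
                                                cfg$subject_cv)),
                               cfg$jitter_fields)
      cells <- expand.grid(rule = c("old", "new"), side = c("left", "right"),
                           rep = seq_len(cfg$n_per_cell),
                           stringsAsFactors = FALSE)
      cells <- cells[sample.int(nrow(cells)), ]
      for (k in seq_len(nrow(cells))) {
        # a jittered parameter set can be dynamically infeasible (e.g. a
        # countermovement dip too violent for positive ground contact);
        # such dives cannot be executed, so redraw the trial jitter --
        # the trial population is conditioned on physical validity
        params <- NULL
        for (attempt in 1:100) {
          tmult <- exp(stats::rnorm(length(cfg$jitter_fields), 0, cfg$trial_cv))
          args <- cfg$base
          for (j in seq_along(cfg$jitter_fields)) {
            f <- cfg$jitter_fields[j]
            base_val <- if (!is.null(args[[f]])) args[[f]] else
              formals(sim_params)[[f]]
            args[[f]] <- base_val * smult[[f]] * tmult[j]
          }
          args$body_mass_kg <- sub$body_mass_kg
          args$rule <- cells$rule[k]
          args$side <- cells$side[k]
          args$frontal_step_m <- if (cells$rule[k] == "new") cfg$frontal_step_m else 0
          args$noise_sd_pos_m <- cfg$noise_sd_pos_m
          args$noise_sd_force_n <- cfg$noise_sd_force_n
          args$seed <- sample.int(.Machine$integer.max - 1L, 1L)
          params <- tryCatch(do.call(sim_params, args), error = function(e) NULL)
          if (!is.null(params)) break
        }
        if (is.null(params))
          stop("simulate_session: could not draw a feasible trial parameter set in 100 attempts; baseline parameters are too close to a physical limit")
        quality <- if (cfg$discard_rate > 0 &&
                       stats::runif(1) < cfg$discard_rate) "discarded" else "ok"
        if (compute_truth) {
          sd <- simulate_dive(params,
                              trial_id = sprintf("%s_T%02d", sub$subject_id, k),
                              subject_id = sub$subject_id,
                              iplag_score = sub$iplag_score, quality = quality)
          tr <- sd$trial
        } else {
          tr <- simulate_dive_fast(params,
                                   trial_id = sprintf("%s_T%02d", sub$subject_id, k),
                                   subject_id = sub$subject_id,
                                   iplag_score = sub$iplag_score,
                                   quality = quality)
        }
        trials[[length(trials) + 1L]] <- tr
      }
    }
    trials
  })
}

# sampling-only variant (no ground-truth channel); used by replicate studies
simulate_dive_fast <- function(params, trial_id, subject_id, iplag_score,
                               quality = "ok") {
  m <- make_dive_model(params)
  n_kin <- floor(m$t_end * params$kin_rate_hz) + 1L
  t_kin <- (seq_len(n_kin) - 1L) / params$kin_rate_hz
  f_t0 <- 0.5 / params$force_rate_hz
  n_frc <- floor((m$t_end - f_t0) * params$force_rate_hz) + 1L
  t_frc <- f_t0 + (seq_len(n_frc) - 1L) / params$force_rate_hz
  pos <- m$pos(t_kin)
  frc <- m$force(t_frc)
  sgn <- if (params$side == "left") -1 else 1
  pos[, 1L] <- sgn * pos[, 1L]
  frc[, 1L] <- sgn * frc[, 1L]
  with_seed(params$seed, {
    if (params$noise_sd_pos_m > 0)
      pos <- pos + matrix(stats::rnorm(length(pos), 0, params$noise_sd_pos_m),
                          nrow = nrow(pos))
    if (params$noise_sd_force_n > 0)
      frc <- frc + matrix(stats::rnorm(length(frc), 0, params$noise_sd_force_n),
                          nrow = nrow(frc))
  })
  trial_record(trial_id, subject_id, params$body_mass_kg, params$rule,
               params$side, iplag_score, quality,
               cm = uniform_series(pos, rate = params$kin_rate_hz, t0 = 0),
               grf = uniform_series(frc, rate = params$force_rate_hz, t0 = f_t0))
}
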