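# Per-trial processing: filtering, event detection and the 14 outcome
# variables, plus the batch driver with structured exclusion logging.

#' Names of the 14 dive outcome variables
#'
#' Displacements (m): VD, MLD, APD, RD; velocities (m/s): AV, PV;
#' weight-normalised peak forces (xBW): VPF, MLPF, APPF, RPF;
#' weight-normalised impulses (xBW.s): VI, MLI, API, RI.
#'
#' @return character vector of length 14.
#' @export
dive_variable_names <- function() {
  c("VD", "MLD", "APD", "RD", "AV", "PV",
    "VPF", "MLPF", "APPF", "RPF", "VI", "MLI", "API", "RI")
}

#' Filter configuration
#'
#' @param cutoff_hz `"auto"` (residual analysis per trial and channel, the
#'   default), a number in Hz forced on both channels, `"none"` to disable
#'   filtering, or a list with elements `kin` and `force` (each `"auto"`,
#'   `"none"` or a number) for channel-specific settings.
#' @param order net Butterworth order (default 4, zero-lag dual pass).
#' @param grid_hz candidate grid for residual analysis.
#' @return a `filter_config` list.
#' @export
filter_config <- function(cutoff_hz = "auto", order = 4L, grid_hz = 1:40) {
  if (!is.list(cutoff_hz)) cutoff_hz <- list(kin = cutoff_hz, force = cutoff_hz)
  stopifnot(all(c("kin", "force") %in% names(cutoff_hz)))
  structure(list(cutoff_hz = cutoff_hz, order = as.integer(order),
                 grid_hz = grid_hz),
            class = "filter_config")
}

# filter one channel according to the config; returns the filtered series
# and the cutoff actually used (NA when filtering is off)
apply_channel_filter <- function(x, spec, fcfg) {
  if (identical(spec, "none")) return(list(series = x, cutoff = NA_real_))
  cutoff <- if (identical(spec, "auto")) {
    residual_analysis_cutoff(x, grid_hz = fcfg$grid_hz, order = fcfg$order)
  } else as.numeric(spec)
  list(series = butterworth_lowpass(x, cutoff, order = fcfg$order),
       cutoff = cutoff)
}

#' Compute the 14 outcome variables of one trial
#'
#' Filters both channels (independently configurable), detects the dive
#' window on the filtered CM trajectory and the impulse phase on the
#' filtered force signal, and computes all displacement, velocity, peak
#' force and impulse outcomes.
#'
#' @param trial a [trial_record()].
#' @param filter a [filter_config()].
#' @param onset_factor,contact_threshold_n impulse-phase thresholds, see
#'   [detect_impulse_phase()].
#' @return a list with the 14 variables, the detected `window` and `phase`,
#'   and the per-channel `cutoffs` used (NA = unfiltered).
#' @export
process_trial <- function(trial, filter = filter_config(),
                          onset_factor = 1.05, contact_threshold_n = 10) {
  stopifnot(inherits(trial, "trial_record"), inherits(filter, "filter_config"))
  fk <- apply_channel_filter(trial$cm, filter$cutoff_hz$kin, filter)
  ff <- apply_channel_filter(trial$grf, filter$cutoff_hz$force, filter)
  kin <- kinematic_outcomes(fk$series)
  kin0 <- kin[dive_variable_names()[1:6]]
  kin0_ok <- all(vapply(kin0, function(v) is.finite(v), logical(1)))
  if (!kin0_ok) stop("process_trial: non-finite kinematic outcome")
  kqn <- kinetic_outcomes(ff$series, trial$body_mass_kg, onset_factor,
                          contact_threshold_n)
  out <- c(kin[c("VD", "MLD", "APD", "RD", "AV", "PV")],
           kqn[c("VPF", "MLPF", "APPF", "RPF", "VI", "MLI", "API", "RI")])
  c(out, list(window = kin$window, phase = kqn$phase,
              cutoffs = c(kin = fk$cutoff, force = ff$cutoff)))
}

#' Process a batch of trials
#'
#' Runs [process_trial()] on every `"ok"` trial; trials flagged
#' `"discarded"` or failing event detection are excluded and logged with a
#' machine-readable reason code.
#'
#' @param trials list of [trial_record()]s.
#' @inheritParams process_trial
#' @return a data.frame with one row per analysed trial (metadata plus the
#'   14 variables), with attributes `exclusions` (data.frame of
#'   `trial_id`, `reason`, `message`) and `cutoffs` (per-trial cutoffs
#'   used).
#' @export
process_trials <- function(trials, filter = filter_config(),
                           onset_factor = 1.05, contact_threshold_n = 10) {
  vn <- dive_variable_names()
  vals <- matrix(NA_real_, length(trials), length(vn),
                 dimnames = list(NULL, vn))
  keep <- logical(length(trials))
  excl <- list()
  cuts <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    if (tr$quality != "ok") {
      excl[[length(excl) + 1L]] <- data.frame(
        trial_id = tr$trial_id, reason = "discarded_quality",
        message = "flagged discarded upstream (capture problems)",
        stringsAsFactors = FALSE)
      next
    }
    res <- tryCatch(process_trial(tr, filter, onset_factor, contact_threshold_n),
                    error = function(e) e)
    if (inherits(res, "error")) {
      reason <- if (grepl("no rising phase", conditionMessage(res)))
        "no_rising_phase"
      else if (grepl("no impulse detected", conditionMessage(res)))
        "no_impulse"
      else if (grepl("no takeoff detected", conditionMessage(res)))
        "no_takeoff"
      else "processing_error"
      excl[[length(excl) + 1L]] <- data.frame(
        trial_id = tr$trial_id, reason = reason,
        message = conditionMessage(res), stringsAsFactors = FALSE)
      next
    }
    cuts[[length(cuts) + 1L]] <- data.frame(
      trial_id = tr$trial_id, cutoff_kin_hz = res$cutoffs[["kin"]],
      cutoff_force_hz = res$cutoffs[["force"]], stringsAsFactors = FALSE)
    vals[i, ] <- vapply(vn, function(v) res[[v]], numeric(1))
    keep[i] <- TRUE
  }
  meta <- function(f) vapply(trials, function(tr) tr[[f]], character(1))
  out <- data.frame(trial_id = meta("trial_id")[keep],
                    subject_id = meta("subject_id")[keep],
                    body_mass_kg = vapply(trials, function(tr) tr$body_mass_kg,
                                          numeric(1))[keep],
                    rule = meta("rule")[keep], side = meta("side")[keep],
                    iplag_score = vapply(trials, function(tr) tr$iplag_score,
                                         integer(1))[keep],
                    vals[keep, , drop = FALSE],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "exclusions") <- if (length(excl)) do.call(rbind, excl) else
    data.frame(trial_id = character(), reason = character(),
               message = character(), stringsAsFactors = FALSE)
  attr(out, "cutoffs") <- if (length(cuts)) do.call(rbind, cuts) else NULL
  out
}
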