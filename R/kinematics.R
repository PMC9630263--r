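# Dive-window detection and the displacement / velocity outcomes.
#
# The dive window runs from the global minimum of the CM vertical
# coordinate (countermovement bottom) to its global maximum (flight apex);
# displacements are absolute per-axis coordinate differences between the
# window ends, the resultant is their Euclidean norm, average velocity is
# resultant displacement over window duration, and peak velocity is the
# maximum instantaneous resultant CM speed inside the window.

#' Detect the dive window from the CM vertical coordinate
#'
#' Returns the sample indices (and times) of the global minimum and global
#' maximum of the vertical (z) CM coordinate; first occurrence wins on exact
#' ties.  The series should be filtered first.
#'
#' @param cm a 3-axis [uniform_series()] of CM position (x, y, z).
#' @return a `dive_window` list with `i_start`, `i_end`, `t_start`, `t_end`.
#' @export
detect_dive_window <- function(cm) {
  stopifnot(inherits(cm, "uniform_series"), ncol(cm$values) == 3L)
  if (nrow(cm$values) < 3L) stop("detect_dive_window: need at least 3 samples")
  z <- cm$values[, 3L]
  i_start <- which.min(z)
  i_end <- which.max(z)
  if (i_start >= i_end)
    stop("detect_dive_window: no rising phase (vertical minimum does not precede maximum); trial should be excluded")
  tt <- series_time(cm)
  structure(list(i_start = i_start, i_end = i_end,
                 t_start = tt[i_start], t_end = tt[i_end]),
            class = "dive_window")
}

#' Per-axis dive displacements
#'
#' Absolute CM coordinate differences between the window end and start:
#' vertical (VD) from z, mediolateral (MLD) from x (transversal),
#' anteroposterior (APD) from y (sagittal), in metres.  Absolute values
#' make left and right dives directly comparable.
#'
#' @param cm a 3-axis [uniform_series()] of CM position.
#' @param w a `dive_window` from [detect_dive_window()].
#' @return named numeric vector `c(VD, MLD, APD)` in metres.
#' @export
displacement_components <- function(cm, w) {
  stopifnot(inherits(cm, "uniform_series"), inherits(w, "dive_window"))
  d <- abs(cm$values[w$i_end, ] - cm$values[w$i_start, ])
  c(VD = unname(d[3L]), MLD = unname(d[1L]), APD = unname(d[2L]))
}

#' Resultant dive displacement
#'
#' Euclidean norm of the three displacement components.
#'
#' @param VD,MLD,APD nonnegative displacements in metres.
#' @return resultant displacement RD in metres.
#' @export
resultant_displacement <- function(VD, MLD, APD) {
  stopifnot(VD >= 0, MLD >= 0, APD >= 0)
  sqrt(VD^2 + MLD^2 + APD^2)
}

#' Average dive velocity
#'
#' Resultant displacement divided by the time spent on the displacement
#' (window duration).
#'
#' @param RD resultant displacement, m.
#' @param w a `dive_window`.
#' @return average velocity AV in m/s.
#' @export
average_velocity <- function(RD, w) {
  stopifnot(inherits(w, "dive_window"), w$t_end > w$t_start)
  RD / (w$t_end - w$t_start)
}

#' Peak dive velocity
#'
#' Maximum instantaneous resultant CM speed over the window: each axis is
#' differentiated ([differentiate()]), the sample-wise Euclidean norm taken,
#' and the maximum over `[i_start, i_end]` returned.
#'
#' @param cm a 3-axis [uniform_series()] of CM position.
#' @param w a `dive_window`.
#' @return peak velocity PV in m/s.
#' @export
peak_velocity <- function(cm, w) {
  stopifnot(inherits(cm, "uniform_series"), inherits(w, "dive_window"))
  v <- differentiate(cm)$values
  speed <- sqrt(rowSums(v^2))
  max(speed[w$i_start:w$i_end])
}

#' All kinematic outcomes of one trial
#'
#' Convenience wrapper: window detection plus the six displacement/velocity
#' variables.
#'
#' @param cm a 3-axis [uniform_series()] of (filtered) CM position.
#' @return named list with `VD`, `MLD`, `APD`, `RD`, `AV`, `PV` and the
#'   detected `window`.
#' @export
kinematic_outcomes <- function(cm) {
  w <- detect_dive_window(cm)
  d <- displacement_components(cm, w)
  RD <- resultant_displacement(d[["VD"]], d[["MLD"]], d[["APD"]])
  list(VD = d[["VD"]], MLD = d[["MLD"]], APD = d[["APD"]], RD = RD,
       AV = average_velocity(RD, w), PV = peak_velocity(cm, w), window = w)
}
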