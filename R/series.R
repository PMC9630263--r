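#' Uniformly sampled signal
#'
#' Container for a regularly sampled signal: a start time, a sampling rate
#' and a numeric matrix of samples (one column per axis).  Kinematic series
#' hold CM position in metres on the motion-capture clock (nominally 400 Hz),
#' kinetic series hold ground-reaction force in newtons on the force-plate
#' clock (nominally 2000 Hz).  The two clocks are independent; nothing in the
#' pipeline assumes shared timestamps.
#'
#' @param values numeric vector (one axis) or matrix with one column per
#'   axis.  Axis order throughout the package is x (transversal /
#'   mediolateral), y (sagittal / anteroposterior), z (longitudinal /
#'   vertical).
#' @param rate sampling rate in Hz, positive scalar.
#' @param t0 time of the first sample in seconds.
#' @return an object of class `uniform_series`.
#' @examples
#' s <- uniform_series(sin(2 * pi * 1 * (0:399) / 400), rate = 400)
#' head(series_time(s))
#' @export
uniform_series <- function(values, rate, t0 = 0) {
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("uniform_series: 'rate' must be a positive finite scalar (Hz)")
  if (is.null(dim(values)))
    values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) == 0L)
    stop("uniform_series: empty series")
  if (anyNA(values))
    stop("uniform_series: missing samples are not allowed; resolve gaps upstream or flag the trial")
  structure(list(t0 = as.numeric(t0), rate = as.numeric(rate), values = values),
            class = "uniform_series")
}

#' Sample times of a uniform series
#'
#' @param x a `uniform_series`.
#' @return numeric vector of sample times in seconds.
#' @export
series_time <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  x$t0 + (seq_len(nrow(x$values)) - 1L) / x$rate
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %d samples x %d axes @ %g Hz, t0 = %g s\n",
              nrow(x$values), ncol(x$values), x$rate, x$t0))
  invisible(x)
}

#' @export
length.uniform_series <- function(x) nrow(x$values)

# internal: replace the sample matrix, keeping the clock
series_with_values <- function(x, values) {
  uniform_series(values, rate = x$rate, t0 = x$t0)
}
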