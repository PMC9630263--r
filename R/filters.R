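# Low-pass filtering and numerical differentiation shared by the kinematic
# and kinetic stages.  No external DSP dependency: the Butterworth design
# (analog prototype poles -> bilinear transform with prewarping) and the
# zero-lag forward-backward application are implemented here on top of
# stats::filter.

# polynomial coefficients (descending powers, leading 1) from roots
poly_from_roots <- function(r) {
  coef <- 1 + 0i
  for (ri in r) coef <- c(coef, 0) - ri * c(0, coef)
  coef
}

# Butterworth low-pass (b, a) for a digital filter at sampling rate fs.
# Bilinear transform with frequency prewarping so the -3 dB point of the
# single pass sits at cutoff_hz.
butter_coef <- function(order, cutoff_hz, rate_hz) {
  stopifnot(order >= 1, cutoff_hz > 0, cutoff_hz < rate_hz / 2)
  fs <- rate_hz
  warped <- 2 * fs * tan(pi * cutoff_hz / fs)
  k <- seq_len(order)
  p_a <- warped * exp(1i * pi * (2 * k + order - 1) / (2 * order))
  p_z <- (2 * fs + p_a) / (2 * fs - p_a)
  gain <- Re(prod(complex(real = warped, imaginary = 0) / (2 * fs - p_a)))
  b <- gain * Re(poly_from_roots(rep(-1 + 0i, order)))
  a <- Re(poly_from_roots(p_z))
  # enforce exact unit DC gain against roundoff
  b <- b * (sum(a) / sum(b))
  list(b = b, a = a)
}

# single forward pass of the IIR filter with zero initial conditions;
# x is a matrix (columns filtered independently).  The FIR numerator is a
# shifted vector sum; the AR denominator runs through stats::filter's C
# recursion, once for all columns.
iir_pass <- function(b, a, x) {
  n <- nrow(x)
  v <- b[1L] * x
  for (k in seq_len(length(b) - 1L))
    if (n > k) v[(k + 1L):n, ] <- v[(k + 1L):n, ] + b[k + 1L] * x[1:(n - k), , drop = FALSE]
  y <- stats::filter(v, filter = -a[-1L], method = "recursive")
  matrix(as.numeric(y), nrow = n)
}

# forward-backward pass with odd-reflection end padding (length pad_len);
# hot loop implemented in C
filtfilt_mat <- function(b, a, x, pad_len) {
  .Call(divekin_filtfilt, x, as.numeric(b), as.numeric(a),
        as.integer(pad_len))
}

#' Zero-lag Butterworth low-pass filter
#'
#' Filters each axis of a uniformly sampled series with a digital
#' Butterworth low-pass filter.  By default the filter is applied forward
#' and backward (dual pass) so the net phase shift is zero and event timing
#' is preserved; the stated `order` is then the *net* order (each pass uses
#' `order/2`), and the per-pass design cutoff is raised so that the -3 dB
#' point of the combined response sits at the requested `cutoff_hz` (for a
#' fourth-order zero-lag filter this is the classic 1/0.802 correction).
#'
#' @param x a [uniform_series()].
#' @param cutoff_hz requested effective cutoff frequency in Hz; must lie
#'   strictly below the Nyquist frequency `rate/2`.
#' @param order net filter order (default 4).  Must be even when
#'   `zero_lag = TRUE`.
#' @param zero_lag logical; dual-pass zero-phase filtering (default) or a
#'   single causal pass.
#' @param correct_cutoff logical; apply the dual-pass cutoff correction
#'   (default `TRUE` when `zero_lag`).  Ignored for single-pass filtering.
#' @return a filtered `uniform_series` on the same clock.
#' @examples
#' t <- (0:799) / 400
#' s <- uniform_series(sin(2 * pi * 1 * t), rate = 400)
#' f <- butterworth_lowpass(s, cutoff_hz = 10)
#' max(abs(f$values - s$values))  # 1 Hz passes almost unchanged
#' @export
butterworth_lowpass <- function(x, cutoff_hz, order = 4L, zero_lag = TRUE,
                                correct_cutoff = zero_lag) {
  stopifnot(inherits(x, "uniform_series"))
  nyq <- x$rate / 2
  if (!is.numeric(cutoff_hz) || length(cutoff_hz) != 1L || cutoff_hz <= 0 ||
      cutoff_hz >= nyq)
    stop(sprintf("butterworth_lowpass: cutoff %.6g Hz must lie in (0, Nyquist = %.6g Hz)",
                 cutoff_hz, nyq))
  n <- nrow(x$values)
  if (n < 3L * order)
    stop(sprintf("butterworth_lowpass: series too short (%d samples) for order-%d filtering (need >= %d)",
                 n, order, 3L * order))
  if (zero_lag) {
    if (order %% 2L != 0L)
      stop("butterworth_lowpass: net order must be even for zero-lag (dual-pass) filtering")
    m <- order %/% 2L
    fd <- if (correct_cutoff) cutoff_hz / (sqrt(2) - 1)^(1 / (2 * m)) else cutoff_hz
    if (fd >= nyq)
      stop(sprintf("butterworth_lowpass: dual-pass corrected cutoff %.6g Hz reaches Nyquist %.6g Hz",
                   fd, nyq))
    co <- butter_coef(m, fd, x$rate)
    pad <- max(3L * (length(co$a) + length(co$b)),
               as.integer(ceiling(3 * x$rate / cutoff_hz)))
    out <- filtfilt_mat(co$b, co$a, x$values, pad)
  } else {
    co <- butter_coef(order, cutoff_hz, x$rate)
    out <- iir_pass(co$b, co$a, x$values)
  }
  series_with_values(x, out)
}

#' Cutoff selection by residual analysis
#'
#' Winter-style residual analysis: for every candidate cutoff the RMS
#' residual between the raw and low-pass filtered series is computed (pooled
#' over all axes); a straight line is fitted to the residual curve over its
#' high-frequency, noise-dominated region; the selected cutoff is the lowest
#' candidate whose residual has fallen to the fitted line's zero-frequency
#' intercept (the estimated noise floor).  Deterministic given the input and
#' grid, and invariant to amplitude scaling of the signal.
#'
#' @param x a [uniform_series()].
#' @param grid_hz strictly increasing candidate cutoffs in Hz, all below
#'   Nyquist (default 1-40 Hz).
#' @param noise_fraction fraction of the grid (from the top) regarded as
#'   noise-dominated for the straight-line fit; default 0.5.
#' @param order,zero_lag passed to [butterworth_lowpass()].
#' @return the selected cutoff in Hz.  Degenerate inputs (flat residual
#'   curve, e.g. a noise-free band-limited signal) return the grid minimum
#'   with a warning.
#' @export
residual_analysis_cutoff <- function(x, grid_hz = 1:40, noise_fraction = 0.5,
                                     order = 4L, zero_lag = TRUE) {
  stopifnot(inherits(x, "uniform_series"))
  grid_hz <- as.numeric(grid_hz)
  if (length(grid_hz) < 4L || any(diff(grid_hz) <= 0))
    stop("residual_analysis_cutoff: grid must be strictly increasing with >= 4 candidates")
  if (grid_hz[1L] <= 0 || grid_hz[length(grid_hz)] >= x$rate / 2)
    stop("residual_analysis_cutoff: grid must lie within (0, Nyquist)")
  res <- vapply(grid_hz, function(fc) {
    xf <- butterworth_lowpass(x, fc, order = order, zero_lag = zero_lag)
    sqrt(mean((x$values - xf$values)^2))
  }, numeric(1))
  scale <- sqrt(mean(x$values^2))
  k <- length(grid_hz)
  # degenerate: residual at the top of the grid indistinguishable from zero
  # (noise-free input -- there is no noise floor to intersect)
  if (res[k] <= 1e-4 * max(scale, 1e-300)) {
    warning("residual_analysis_cutoff: no measurable noise floor (noise-free input?); returning grid minimum")
    return(grid_hz[1L])
  }
  n_noise <- max(2L, floor(k * noise_fraction))
  idx <- (k - n_noise + 1L):k
  fit <- stats::lm.fit(cbind(1, grid_hz[idx]), res[idx])
  intercept <- fit$coefficients[1L]
  slope <- fit$coefficients[2L]
  if (!is.finite(intercept) || intercept <= 0 || slope >= 0) {
    warning("residual_analysis_cutoff: degenerate noise-line fit; returning grid minimum")
    return(grid_hz[1L])
  }
  below <- which(res <= intercept)
  if (length(below) == 0L) {
    warning("residual_analysis_cutoff: no candidate residual fell to the noise intercept; returning grid maximum")
    return(grid_hz[k])
  }
  grid_hz[min(below)]
}

#' Numerical differentiation of a uniform series
#'
#' Central differences in the interior, first-order one-sided differences at
#' the two ends.  Exact for linear signals; applied per axis.
#'
#' @param x a [uniform_series()] with at least 3 samples.
#' @return a `uniform_series` of derivatives on the same clock.
#' @export
differentiate <- function(x) {
  stopifnot(inherits(x, "uniform_series"))
  n <- nrow(x$values)
  if (n < 3L) stop("differentiate: need at least 3 samples")
  v <- x$values
  r <- x$rate
  d <- rbind((v[2L, ] - v[1L, ]) * r,
             (v[3:n, , drop = FALSE] - v[1:(n - 2L), , drop = FALSE]) * (r / 2),
             (v[n, ] - v[n - 1L, ]) * r)
  series_with_values(x, d)
}

# trapezoidal integral of y over uniformly spaced samples with spacing dt
trapz_uniform <- function(y, dt) {
  n <- length(y)
  if (n < 2L) return(0)
  dt * (sum(y) - (y[1L] + y[n]) / 2)
}
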