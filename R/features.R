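#' Signal magnitude vector
#'
#' Per-sample Euclidean norm of the three acceleration components,
#' `sqrt(ax^2 + ay^2 + az^2)`.  Orientation-invariant, which matters
#' when many subjects wear the sensor slightly differently.
#'
#' @param samples An n x 3 matrix (or length-3 vector) of accelerations.
#' @return Numeric vector of per-sample magnitudes (>= 0).
#' @export
smv <- function(samples) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 3)
  sqrt(rowSums(samples^2))
}

#' Signal magnitude area
#'
#' Sum over the window of the absolute values of all three axes,
#' `sum(|ax_i| + |ay_i| + |az_i|)`.  Discriminates static from dynamic
#' activities.
#'
#' @param samples An n x 3 matrix of accelerations (n >= 1).
#' @return A single non-negative number.
#' @export
sma <- function(samples) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 3)
  if (nrow(samples) == 0L) stop("empty window")
  sum(abs(samples))
}

#' Root mean square of a series
#' @param x Numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms <- function(x) sqrt(mean(x^2))

#' Composite trapezoidal rule
#'
#' Integrates a uniformly sampled series with spacing `dt` seconds
#' (`dt = 1 / rate_hz` for accelerometer windows).
#'
#' @param x Numeric vector of at least 2 points.
#' @param dt Sample spacing (> 0).
#' @return The integral approximation.
#' @export
trapezoid_integral <- function(x, dt) {
  if (length(x) < 2L) stop("need at least 2 points")
  if (dt <= 0) stop("`dt` must be > 0")
  dt * (sum(x) - (x[1L] + x[length(x)]) / 2)
}

#' Spectral entropy of a series
#'
#' The series is mean-removed, Fourier-transformed, and the one-sided
#' power spectrum over the non-DC bins `k = 1..floor(L/2)` is
#' normalized to a probability distribution `p_k`; the feature is the
#' Shannon entropy `-sum(p_k * log(p_k))` (natural log).  A constant
#' series has zero total power and returns 0 by convention; a pure tone
#' aligned with one bin also gives 0 (all power in one bin), while
#' white noise approaches `log(floor(L/2))`.
#'
#' @param x Numeric vector, length >= 2.
#' @return Entropy in nats (>= 0).
#' @export
spectral_entropy <- function(x) {
  L <- length(x)
  if (L < 2L) stop("need at least 2 points")
  xc <- x - mean(x)
  f <- stats::fft(xc)
  p <- Mod(f[2:(floor(L / 2) + 1L)])^2
  tot <- sum(p)
  if (tot <= .Machine$double.eps * L) return(0)
  p <- p / tot
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Names of the 51 window features
#'
#' Stable identifiers, in schema order: per-axis means and the mean
#' signal magnitude vector; mean log / exp / exp-squared transforms;
#' mean squared acceleration; trapezoidal integrals; minima, maxima,
#' ranges, standard deviations and RMS values for each axis and the
#' SMV; the signal magnitude area; a second mean-square block (the
#' source feature list carries the mean of squared values twice, once
#' as "mean squared acceleration" and once as "mean square" — both
#' slots are retained so the table has exactly 51 columns); spectral
#' entropies; and per-axis medians.
#'
#' @return Character vector of length 51.
#' @export
feature_names <- function() {
  c("mean_x", "mean_y", "mean_z",
    "smv_mean",
    "meanlog_x", "meanlog_y", "meanlog_z",
    "meanexp_x", "meanexp_y", "meanexp_z",
    "meanexpsq_x", "meanexpsq_y", "meanexpsq_z",
    "meansq_x", "meansq_y", "meansq_z",
    "trapz_x", "trapz_y", "trapz_z", "trapz_smv",
    "min_x", "min_y", "min_z", "min_smv",
    "max_x", "max_y", "max_z", "max_smv",
    "range_x", "range_y", "range_z", "range_smv",
    "sd_x", "sd_y", "sd_z", "sd_smv",
    "rms_x", "rms_y", "rms_z", "rms_smv",
    "sma",
    "sqmean_x", "sqmean_y", "sqmean_z",
    "entropy_x", "entropy_y", "entropy_z", "entropy_smv",
    "median_x", "median_y", "median_z")
}

#' Catalogue of the 51 features
#'
#' @return A data frame with columns `slot` (1-51), `name` and
#'   `description`.
#' @export
feature_catalog <- function() {
  data.frame(
    slot = 1:51,
    name = feature_names(),
    description = c(
      rep("mean acceleration in the window", 3),
      "mean signal magnitude vector",
      rep("mean of log(|acc| + eps_log)", 3),
      rep("mean of exp(acc), exponent clipped", 3),
      rep("mean of exp(acc^2), exponent clipped", 3),
      rep("mean squared acceleration", 3),
      rep("trapezoidal integral (dt = 1/rate)", 4),
      rep("minimum", 4), rep("maximum", 4), rep("range (max - min)", 4),
      rep("standard deviation (n-1 divisor)", 4),
      rep("root mean square", 4),
      "signal magnitude area",
      rep("mean square (duplicate slot of the source schema)", 3),
      rep("spectral entropy of the DC-removed power spectrum", 4),
      rep("median", 3)),
    stringsAsFactors = FALSE)
}

#' Extract the 51 features from one window
#'
#' Numerical conventions: the mean-logarithm uses `log(|v| + eps_log)`
#' because raw axis accelerations oscillate around zero where a plain
#' logarithm is undefined; the exponential features clip their exponent
#' argument at `exp_cap` before exponentiation so a single large sample
#' cannot overflow to `Inf`; the standard deviation uses the n-1
#' divisor; the trapezoidal integrals use `dt = 1/rate_hz`.
#'
#' @param samples An L x 3 matrix of accelerations, L >= 2.
#' @param rate_hz Sampling rate in Hz.
#' @param eps_log Offset inside the logarithm (default 1e-9).
#' @param exp_cap Exponent clip value (default 50).
#' @return Named numeric vector of length 51, in [feature_names()]
#'   order.
#' @export
extract_features <- function(samples, rate_hz, eps_log = 1e-9,
                             exp_cap = 50) {
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 3)
  L <- nrow(samples)
  if (L < 2L) stop("window must contain at least 2 samples")
  if (rate_hz <= 0) stop("`rate_hz` must be > 0")
  dt <- 1 / rate_hz
  s <- smv(samples)
  cols4 <- cbind(samples, s)  # x, y, z, smv

  out <- c(
    colMeans(samples),
    mean(s),
    colMeans(log(abs(samples) + eps_log)),
    colMeans(exp(pmin(samples, exp_cap))),
    colMeans(exp(pmin(samples^2, exp_cap))),
    colMeans(samples^2),
    apply(cols4, 2L, trapezoid_integral, dt = dt),
    apply(cols4, 2L, min),
    apply(cols4, 2L, max),
    apply(cols4, 2L, function(v) max(v) - min(v)),
    apply(cols4, 2L, stats::sd),
    apply(cols4, 2L, rms),
    sma(samples),
    colMeans(samples^2),
    apply(cols4, 2L, spectral_entropy),
    apply(samples, 2L, stats::median))
  names(out) <- feature_names()
  out
}
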