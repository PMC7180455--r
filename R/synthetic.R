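#' Activity signal specification
#'
#' Describes the parametric signal model of one activity: a constant
#' per-axis offset (the gravity component as seen by the wrist-worn
#' sensor), a set of sinusoidal components per axis (the quasi-periodic
#' movement signature), stationary Gaussian noise with a prescribed
#' cross-axis correlation structure, and a slow Ornstein-Uhlenbeck
#' baseline drift.  The drift emulates the within-recording
#' non-stationarity of real wrist recordings (posture changes,
#' movement variability): without it, every window of a recording is a
#' near-replica of every other and classification becomes trivially
#' easy, which real accelerometer data is not.
#'
#' @param name Activity label (single string).
#' @param offset Numeric length-3 vector: per-axis base acceleration in
#'   m/s^2 (includes the gravity projection).
#' @param sinusoids Named list with elements `x`, `y`, `z`; each is a
#'   numeric matrix with columns `amp` (m/s^2), `freq` (Hz, > 0) and
#'   `phase` (rad), one row per sinusoidal component.  A 0-row matrix
#'   means no periodic component on that axis.
#' @param noise_sd Per-sample noise standard deviation in m/s^2 (>= 0).
#' @param axis_correlation 3x3 correlation matrix of the per-axis noise
#'   (and drift innovations); must be symmetric with unit diagonal and
#'   positive definite.
#' @param drift_sd Stationary standard deviation (m/s^2, >= 0) of the
#'   baseline drift; 0 disables it.
#' @param drift_tau_s Drift correlation time in seconds (> 0).
#'
#' @return An object of class `activity_spec`.
#' @export
activity_spec <- function(name, offset, sinusoids = empty_sinusoids(),
                          noise_sd = 0.5, axis_correlation = diag(3),
                          drift_sd = 0, drift_tau_s = 5) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  offset <- as.numeric(offset)
  if (length(offset) != 3L || any(!is.finite(offset)))
    stop("`offset` must be 3 finite numbers")
  if (!is.list(sinusoids) || !all(c("x", "y", "z") %in% names(sinusoids)))
    stop("`sinusoids` must be a list with elements x, y, z")
  sinusoids <- lapply(sinusoids[c("x", "y", "z")], function(m) {
    m <- as.matrix(m)
    if (nrow(m) > 0L) {
      if (ncol(m) != 3L) stop("each sinusoid matrix needs columns amp, freq, phase")
      if (any(m[, 2L] <= 0)) stop("sinusoid frequencies must be > 0")
    }
    colnames(m) <- c("amp", "freq", "phase")[seq_len(max(ncol(m), 0L))]
    m
  })
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be a single number >= 0")
  C <- as.matrix(axis_correlation)
  if (!all(dim(C) == c(3L, 3L)))
    stop("`axis_correlation` must be a 3x3 matrix")
  if (!isTRUE(all.equal(C, t(C), tolerance = 1e-8)))
    stop("`axis_correlation` must be symmetric")
  if (any(abs(diag(C) - 1) > 1e-8))
    stop("`axis_correlation` must have unit diagonal")
  if (min(eigen(C, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("`axis_correlation` must be positive definite")
  if (drift_sd < 0) stop("`drift_sd` must be >= 0")
  if (drift_tau_s <= 0) stop("`drift_tau_s` must be > 0")
  structure(list(name = name, offset = offset, sinusoids = sinusoids,
                 noise_sd = noise_sd, axis_correlation = C,
                 drift_sd = drift_sd, drift_tau_s = drift_tau_s),
            class = "activity_spec")
}

#' @rdname activity_spec
#' @export
empty_sinusoids <- function() {
  m <- matrix(numeric(0), 0L, 3L, dimnames = list(NULL, c("amp", "freq", "phase")))
  list(x = m, y = m, z = m)
}

#' Contamination specification
#'
#' Attribute-noise model applied to otherwise clean recordings.
#' Contamination acts on whole window-length segments (not single
#' samples) so that flagged windows correspond one-to-one to injected
#' outliers: each consecutive segment of `segment_s` seconds is
#' independently corrupted with probability `rate`.  A corrupted
#' segment is displaced by a shift whose Euclidean magnitude is that of
#' the vector `mean_shift * noise_sd` but whose direction is drawn
#' uniformly at random per segment — corrupted segments scatter into
#' different regions of the signal space instead of forming a stable,
#' learnable sub-cluster, which is what distinguishes attribute noise
#' from a systematic sensor bias — and its noise is inflated by
#' `scale_inflation`.  In addition,
#' `edge_artifact_s` seconds at each end of the recording can be
#' replaced by a ramped low-variance "learning-curve" signal that
#' emulates a subject settling into the activity.
#'
#' @param rate Probability in \[0, 1\] that a segment is contaminated.
#' @param mean_shift Length-3 vector of per-axis shift magnitudes, in
#'   multiples of the activity's `noise_sd`.
#' @param scale_inflation Multiplicative factor (>= 1) on the noise
#'   standard deviation within contaminated segments.
#' @param edge_artifact_s Duration (s, >= 0) of the ramp artifact at
#'   each recording edge.
#' @param segment_s Segment length in seconds; defaults to the 4-s
#'   analysis window so contaminated segments align with windows.
#'
#' @return An object of class `contamination_spec`.
#' @export
contamination_spec <- function(rate = 0.1, mean_shift = c(6, 6, 6),
                               scale_inflation = 2, edge_artifact_s = 0,
                               segment_s = 4) {
  stopifnot(is.numeric(rate), length(rate) == 1L)
  if (rate < 0 || rate > 1) stop("`rate` must be in [0, 1]")
  mean_shift <- as.numeric(mean_shift)
  if (length(mean_shift) != 3L || any(!is.finite(mean_shift)))
    stop("`mean_shift` must be 3 finite numbers")
  if (scale_inflation < 1) stop("`scale_inflation` must be >= 1")
  if (edge_artifact_s < 0) stop("`edge_artifact_s` must be >= 0")
  if (segment_s <= 0) stop("`segment_s` must be > 0")
  structure(list(rate = rate, mean_shift = mean_shift,
                 scale_inflation = scale_inflation,
                 edge_artifact_s = edge_artifact_s, segment_s = segment_s),
            class = "contamination_spec")
}

#' No-contamination specification
#' @return A `contamination_spec` with rate 0 and no edge artifacts.
#' @export
no_contamination <- function() {
  contamination_spec(rate = 0, mean_shift = c(0, 0, 0),
                     scale_inflation = 1, edge_artifact_s = 0)
}

#' Default activity library
#'
#' Six wrist-accelerometer activity signatures with distinct but
#' partially overlapping frequencies, amplitudes and offsets.  They are
#' configuration, not measurements: parameter values were chosen once so
#' that (a) activities are separable but not trivially so, and (b) the
#' noise level is large enough that covariance structure matters for
#' outlier detection.
#'
#' @return A list of [activity_spec] objects.
#' @export
default_activities <- function() {
  sin1 <- function(ax, ay, az) list(
    x = matrix(ax, ncol = 3, byrow = TRUE,
               dimnames = list(NULL, c("amp", "freq", "phase"))),
    y = matrix(ay, ncol = 3, byrow = TRUE,
               dimnames = list(NULL, c("amp", "freq", "phase"))),
    z = matrix(az, ncol = 3, byrow = TRUE,
               dimnames = list(NULL, c("amp", "freq", "phase"))))
  corr <- function(rxy, rxz, ryz) {
    C <- diag(3); C[1, 2] <- C[2, 1] <- rxy
    C[1, 3] <- C[3, 1] <- rxz; C[2, 3] <- C[3, 2] <- ryz
    C
  }
  list(
    activity_spec("walking", offset = c(0.0, -1.0, 9.6),
                  sinusoids = sin1(c(0.33, 1.9, 0), c(0.24, 1.9, pi / 3),
                                   c(0.15, 3.8, pi / 5)),
                  noise_sd = 0.3, axis_correlation = corr(0.35, 0.15, 0.25),
                  drift_sd = 1.0, drift_tau_s = 3),
    activity_spec("jogging", offset = c(2.6, -3.2, 7.6),
                  sinusoids = sin1(c(0.36, 2.7, 0), c(0.30, 2.7, pi / 4),
                                   c(0.21, 5.4, pi / 7)),
                  noise_sd = 0.3, axis_correlation = corr(0.30, 0.20, 0.30),
                  drift_sd = 1.0, drift_tau_s = 3),
    activity_spec("stepping", offset = c(-2.6, 1.4, 10.2),
                  sinusoids = sin1(c(0.27, 1.4, 0), c(0.21, 1.4, pi / 2),
                                   c(0.21, 2.8, 0)),
                  noise_sd = 0.3, axis_correlation = corr(0.40, 0.10, 0.20),
                  drift_sd = 1.0, drift_tau_s = 3),
    activity_spec("ironing", offset = c(3.0, 1.8, 8.8),
                  sinusoids = sin1(c(0.24, 0.8, 0), c(0.18, 0.8, pi / 2),
                                   c(0.09, 1.6, 0)),
                  noise_sd = 0.3, axis_correlation = corr(0.25, 0.05, 0.15),
                  drift_sd = 1.0, drift_tau_s = 3),
    activity_spec("teeth_brushing", offset = c(-1.6, 3.4, 7.8),
                  sinusoids = sin1(c(0.30, 4.0, 0), c(0.24, 4.0, pi / 3),
                                   c(0.12, 8.0, 0)),
                  noise_sd = 0.3, axis_correlation = corr(0.30, 0.10, 0.20),
                  drift_sd = 1.0, drift_tau_s = 3),
    activity_spec("dishwashing", offset = c(0.8, 0.8, 11.0),
                  sinusoids = sin1(c(0.18, 0.6, 0), c(0.21, 0.9, pi / 6),
                                   c(0.12, 1.2, pi / 2)),
                  noise_sd = 0.3, axis_correlation = corr(0.20, 0.15, 0.10),
                  drift_sd = 1.0, drift_tau_s = 3)
  )
}

#' Dataset generation plan
#'
#' @param subjects Number of subjects per activity; either a single
#'   count applied to every activity or a vector with one count per
#'   activity.
#' @param activities List of [activity_spec] objects.
#' @param duration_s Recording length in seconds (default 120, i.e.
#'   each subject performs each activity for 2 minutes).
#' @param rate_hz Sampling rate in Hz (default 51.2).
#' @param seed Integer master seed; per-recording seeds are derived
#'   from it deterministically.
#'
#' @return An object of class `dataset_plan`.
#' @export
dataset_plan <- function(subjects, activities = default_activities(),
                         duration_s = 120, rate_hz = 51.2, seed = 1L) {
  if (!is.list(activities) || length(activities) == 0L ||
      !all(vapply(activities, inherits, logical(1), "activity_spec")))
    stop("`activities` must be a non-empty list of activity_spec objects")
  subjects <- as.integer(subjects)
  if (length(subjects) == 1L) subjects <- rep(subjects, length(activities))
  if (length(subjects) != length(activities) || any(subjects < 1L))
    stop("`subjects` must give a count >= 1 per activity")
  if (duration_s <= 0) stop("`duration_s` must be > 0")
  if (rate_hz <= 0) stop("`rate_hz` must be > 0")
  structure(list(subjects = subjects, activities = activities,
                 duration_s = duration_s, rate_hz = rate_hz,
                 seed = as.integer(seed)),
            class = "dataset_plan")
}

# Deterministic per-recording seed below 2^31, derived from the master
# seed and the activity/subject indices (parallel-safe streams).
derive_seed <- function(seed, activity_idx, subject_idx) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 +
    activity_idx * 100003 + subject_idx * 7919
  as.integer(s %% 2147483629 + 1)
}

#' Generate one synthetic recording
#'
#' Simulates a triaxial accelerometer recording of one subject
#' performing one activity: per-axis offset plus sinusoids plus
#' correlated Gaussian noise (the correlation is imposed through the
#' symmetric square root of the correlation matrix), with optional
#' segment-level contamination and edge artifacts as described in
#' [contamination_spec].  Fully deterministic given `seed`.
#'
#' @param spec An [activity_spec].
#' @param contamination A [contamination_spec]; defaults to none.
#' @param duration_s,rate_hz Recording length (s) and sampling rate (Hz).
#' @param seed Integer seed.
#' @param subject Subject label stored in the result.
#'
#' @return A `har_recording`: list with `subject`, `activity`,
#'   `rate_hz`, `samples` (n x 3 matrix, columns `ax`, `ay`, `az`,
#'   m/s^2) and `contaminated_segments` (1-based indices of corrupted
#'   window-length segments; ground truth for evaluation).
#' @export
generate_recording <- function(spec, contamination = no_contamination(),
                               duration_s = 120, rate_hz = 51.2,
                               seed = 1L, subject = "S1") {
  stopifnot(inherits(spec, "activity_spec"),
            inherits(contamination, "contamination_spec"))
  if (duration_s <= 0) stop("`duration_s` must be > 0")
  if (rate_hz <= 0) stop("`rate_hz` must be > 0")
  n <- round(duration_s * rate_hz)
  if (n < 1) stop("recording would contain no samples")
  set.seed(as.integer(seed))
  tt <- (seq_len(n) - 1) / rate_hz

  base <- matrix(rep(spec$offset, each = n), n, 3)
  for (a in 1:3) {
    comps <- spec$sinusoids[[a]]
    for (j in seq_len(nrow(comps)))
      base[, a] <- base[, a] +
        comps[j, 1L] * sin(2 * pi * comps[j, 2L] * tt + comps[j, 3L])
  }

  ev <- eigen(spec$axis_correlation, symmetric = TRUE)
  sqrtC <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0))) %*% t(ev$vectors)
  noise <- matrix(stats::rnorm(n * 3), n, 3) %*% sqrtC * spec$noise_sd

  drift <- matrix(0, n, 3)
  if (spec$drift_sd > 0) {
    phi <- exp(-1 / (rate_hz * spec$drift_tau_s))
    innov <- matrix(stats::rnorm(n * 3), n, 3) %*% sqrtC
    d <- innov[1L, ]
    drift[1L, ] <- d
    w <- sqrt(1 - phi^2)
    for (i in 2:n) {
      d <- phi * d + w * innov[i, ]
      drift[i, ] <- d
    }
    drift <- drift * spec$drift_sd
  }
  base <- base + drift

  L <- max(1L, floor(contamination$segment_s * rate_hz))
  nseg <- floor(n / L)
  contaminated <- integer(0)
  if (nseg > 0 && contamination$rate > 0) {
    hit <- stats::runif(nseg) < contamination$rate
    contaminated <- which(hit)
  }
  samples <- base + noise
  shift_mag <- sqrt(sum((contamination$mean_shift * spec$noise_sd)^2))
  for (s in contaminated) {
    idx <- ((s - 1L) * L + 1L):(s * L)
    u <- stats::rnorm(3L)
    u <- u / sqrt(sum(u^2))
    shift <- u * shift_mag
    samples[idx, ] <- base[idx, ] +
      noise[idx, ] * contamination$scale_inflation +
      matrix(rep(shift, each = L), L, 3)
  }

  ne <- round(contamination$edge_artifact_s * rate_hz)
  if (ne > 0) {
    ne <- min(ne, floor(n / 2))
    ramp <- seq(0, 1, length.out = ne)
    low <- matrix(stats::rnorm(ne * 3, sd = 0.05 * max(spec$noise_sd, 1e-3)),
                  ne, 3)
    head_sig <- outer(ramp, spec$offset) + low
    samples[seq_len(ne), ] <- head_sig
    low2 <- matrix(stats::rnorm(ne * 3, sd = 0.05 * max(spec$noise_sd, 1e-3)),
                   ne, 3)
    samples[n - ne + seq_len(ne), ] <- outer(rev(ramp), spec$offset) + low2
  }

  colnames(samples) <- c("ax", "ay", "az")
  structure(list(subject = subject, activity = spec$name, rate_hz = rate_hz,
                 samples = samples, contaminated_segments = contaminated,
                 segment_s = contamination$segment_s),
            class = "har_recording")
}

#' Generate a multi-subject, multi-activity dataset on disk
#'
#' Writes one CSV recording per subject x activity pair (columns
#' `ax,ay,az`, header row), a `manifest.csv` listing every file with
#' its subject, activity and sampling rate, and a `contamination.csv`
#' ground-truth table of contaminated segment indices.  Output is fully
#' reproducible: the same plan, contamination and master seed give
#' byte-identical files.
#'
#' @param plan A [dataset_plan].
#' @param contamination A [contamination_spec].
#' @param out_dir Output directory (created if missing).
#'
#' @return Invisibly, the manifest data frame with an attribute
#'   `contamination` holding the truth table.
#' @export
generate_dataset <- function(plan, contamination = no_contamination(),
                             out_dir) {
  stopifnot(inherits(plan, "dataset_plan"),
            inherits(contamination, "contamination_spec"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  manifest <- list()
  truth <- list()
  for (ai in seq_along(plan$activities)) {
    spec <- plan$activities[[ai]]
    for (si in seq_len(plan$subjects[ai])) {
      subject <- sprintf("S%02d", si)
      rec <- generate_recording(
        spec, contamination, duration_s = plan$duration_s,
        rate_hz = plan$rate_hz, seed = derive_seed(plan$seed, ai, si),
        subject = subject)
      fname <- sprintf("%s_%s.csv", subject, gsub("[^A-Za-z0-9]+", "-", spec$name))
      write_recording(rec, file.path(out_dir, fname))
      manifest[[length(manifest) + 1L]] <- data.frame(
        file = fname, subject = subject, activity = spec$name,
        rate_hz = plan$rate_hz, stringsAsFactors = FALSE)
      if (length(rec$contaminated_segments))
        truth[[length(truth) + 1L]] <- data.frame(
          file = fname, segment = rec$contaminated_segments,
          stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, manifest)
  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(file = character(0), segment = integer(0))
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(truth, file.path(out_dir, "contamination.csv"),
                   row.names = FALSE, quote = FALSE)
  attr(manifest, "contamination") <- truth
  invisible(manifest)
}

#' Generate a dataset in memory
#'
#' Same simulation as [generate_dataset] but returns the recordings as
#' a list instead of writing files; convenient for simulation studies
#' and tests.
#'
#' @inheritParams generate_dataset
#' @return A list of `har_recording` objects.
#' @export
generate_recordings <- function(plan, contamination = no_contamination()) {
  stopifnot(inherits(plan, "dataset_plan"))
  recs <- list()
  for (ai in seq_along(plan$activities)) {
    spec <- plan$activities[[ai]]
    for (si in seq_len(plan$subjects[ai])) {
      recs[[length(recs) + 1L]] <- generate_recording(
        spec, contamination, duration_s = plan$duration_s,
        rate_hz = plan$rate_hz, seed = derive_seed(plan$seed, ai, si),
        subject = sprintf("S%02d", si))
    }
  }
  recs
}
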