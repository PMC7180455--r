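# Independent brute-force oracles used across the test files.  These
# deliberately avoid the package's vectorized implementations: plain
# loops, explicit formulas, explicit matrix inverses.

# Loop-based computation of all 51 window features.
oracle_features <- function(w, rate_hz, eps_log = 1e-9, exp_cap = 50) {
  L <- nrow(w)
  dt <- 1 / rate_hz
  smv_i <- numeric(L)
  for (i in seq_len(L)) smv_i[i] <- sqrt(w[i, 1]^2 + w[i, 2]^2 + w[i, 3]^2)
  msum <- function(v) { s <- 0; for (x in v) s <- s + x; s / length(v) }
  o_sd <- function(v) { m <- msum(v); s <- 0; for (x in v) s <- s + (x - m)^2
    sqrt(s / (length(v) - 1)) }
  o_trap <- function(v) { s <- 0
    for (i in 1:(length(v) - 1)) s <- s + (v[i] + v[i + 1]) / 2 * dt; s }
  o_rms <- function(v) { s <- 0; for (x in v) s <- s + x^2
    sqrt(s / length(v)) }
  o_median <- function(v) stats::median(v)
  o_entropy <- function(v) {
    m <- msum(v); vc <- v - m
    K <- floor(L / 2)
    p <- numeric(K)
    n_idx <- 0:(L - 1)
    for (k in 1:K) {
      re <- sum(vc * cos(-2 * pi * k * n_idx / L))
      im <- sum(vc * sin(-2 * pi * k * n_idx / L))
      p[k] <- re^2 + im^2
    }
    tot <- sum(p)
    if (tot <= .Machine$double.eps * L) return(0)
    p <- p / tot
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ax <- w[, 1]; ay <- w[, 2]; az <- w[, 3]
  sma_v <- 0
  for (i in seq_len(L)) sma_v <- sma_v + abs(ax[i]) + abs(ay[i]) + abs(az[i])
  out <- c(
    msum(ax), msum(ay), msum(az),
    msum(smv_i),
    msum(log(abs(ax) + eps_log)), msum(log(abs(ay) + eps_log)),
    msum(log(abs(az) + eps_log)),
    msum(exp(pmin(ax, exp_cap))), msum(exp(pmin(ay, exp_cap))),
    msum(exp(pmin(az, exp_cap))),
    msum(exp(pmin(ax^2, exp_cap))), msum(exp(pmin(ay^2, exp_cap))),
    msum(exp(pmin(az^2, exp_cap))),
    msum(ax^2), msum(ay^2), msum(az^2),
    o_trap(ax), o_trap(ay), o_trap(az), o_trap(smv_i),
    min(ax), min(ay), min(az), min(smv_i),
    max(ax), max(ay), max(az), max(smv_i),
    max(ax) - min(ax), max(ay) - min(ay), max(az) - min(az),
    max(smv_i) - min(smv_i),
    o_sd(ax), o_sd(ay), o_sd(az), o_sd(smv_i),
    o_rms(ax), o_rms(ay), o_rms(az), o_rms(smv_i),
    sma_v,
    msum(ax^2), msum(ay^2), msum(az^2),
    o_entropy(ax), o_entropy(ay), o_entropy(az), o_entropy(smv_i),
    o_median(ax), o_median(ay), o_median(az))
  names(out) <- feature_names()
  out
}

# Explicit-inverse Mahalanobis distances with mean/covariance computed
# by hand (n-1 divisor).
oracle_mahalanobis <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  mu <- numeric(p)
  for (j in seq_len(p)) mu[j] <- sum(X[, j]) / n
  V <- matrix(0, p, p)
  for (j in seq_len(p)) for (k in seq_len(p))
    V[j, k] <- sum((X[, j] - mu[j]) * (X[, k] - mu[k])) / (n - 1)
  Vinv <- solve(V)
  out <- numeric(n)
  for (i in seq_len(n)) {
    d <- X[i, ] - mu
    out[i] <- sqrt(drop(t(d) %*% Vinv %*% d))
  }
  out
}

# Entropy / symmetrical-uncertainty arithmetic from first principles,
# over explicitly enumerated joint frequencies.
oracle_su <- function(x, y) {
  h <- function(v) {
    tab <- table(v)
    p <- tab / sum(tab)
    -sum(p * log(p))
  }
  hx <- h(x); hy <- h(y)
  if (hx + hy == 0) return(0)
  hxy <- h(paste(x, y, sep = "\r"))
  2 * (hx + hy - hxy) / (hx + hy)
}

# Exhaustive best-subset search over cfs_merit (checks the search
# strategy against full enumeration; feasible up to ~12 features).
oracle_exhaustive_cfs <- function(table, features, class_col = "activity") {
  best <- list(merit = 0, subset = character(0))
  k <- length(features)
  for (m in 1:(2^k - 1)) {
    subset <- features[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
    merit <- cfs_merit(table, subset, class_col)
    if (merit > best$merit + 1e-10) best <- list(merit = merit, subset = subset)
  }
  best
}

# Small labelled feature table with informative and noise columns.
make_toy_table <- function(n_per_class = 20, classes = c("a", "b", "c"),
                           n_noise = 3, seed = 1) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  cls <- rep(classes, each = n_per_class)
  df <- data.frame(subject = "S1", activity = cls,
                   window = seq_len(n) - 1L, stringsAsFactors = FALSE)
  df$inf1 <- as.integer(factor(cls)) + rnorm(n, sd = 0.15)
  for (j in seq_len(n_noise)) df[[paste0("noise", j)]] <- rnorm(n)
  df
}

# Small genuine feature table (two activities, one subject each).
make_toy_recording_table <- function(seed = 8) {
  plan <- dataset_plan(subjects = 1, activities = default_activities()[1:2],
                       duration_s = 30, seed = seed)
  build_feature_table(generate_recordings(plan, no_contamination()))
}

# Study-scale contaminated dataset shared by the heavier tests;
# computed once per test run.
study_fixture_env <- new.env(parent = emptyenv())
study_fixture <- function() {
  if (!exists("fx", envir = study_fixture_env)) {
    plan <- dataset_plan(subjects = 5, duration_s = 120, rate_hz = 51.2,
                         seed = 20)
    recs <- generate_recordings(plan, contamination_spec())
    ft <- build_feature_table(recs)
    truth <- unlist(lapply(recs, function(r) {
      k <- floor(nrow(r$samples) / floor(4 * r$rate_hz))
      seq_len(k) %in% r$contaminated_segments
    }))
    assign("fx", list(recordings = recs, table = ft, contaminated = truth),
           envir = study_fixture_env)
  }
  get("fx", envir = study_fixture_env)
}
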