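# Correlation-based feature subset selection (CFS) with forward
# best-first search, in the style of the Weka supervised attribute
# selector: feature-class and feature-feature associations are measured
# by symmetrical uncertainty after equal-width discretization, and a
# subset's merit is k * rcf / sqrt(k + k (k - 1) * rff).

# Equal-width discretization into `bins` bins; constant columns map to
# a single bin.
discretize_ew <- function(x, bins = 10L) {
  if (is.factor(x) || is.character(x)) return(as.integer(factor(x)))
  rng <- range(x)
  if (!all(is.finite(rng)) || diff(rng) == 0) return(rep(1L, length(x)))
  b <- seq(rng[1L], rng[2L], length.out = bins + 1L)
  findInterval(x, b, rightmost.closed = TRUE, all.inside = TRUE)
}

entropy_counts <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# Symmetrical uncertainty of two discretized vectors:
# 2 * (H(X) + H(Y) - H(X,Y)) / (H(X) + H(Y)); 0 when both are constant.
symmetrical_uncertainty <- function(x, y) {
  hx <- entropy_counts(tabulate(x))
  hy <- entropy_counts(tabulate(y))
  if (hx + hy == 0) return(0)
  hxy <- entropy_counts(as.vector(table(x, y)))
  max(0, min(1, 2 * (hx + hy - hxy) / (hx + hy)))
}

# Precompute the feature-class SU vector and feature-feature SU matrix
# once per table; the best-first search then evaluates subsets with
# plain arithmetic.
cfs_cache <- function(table, features, class_col, bins = 10L) {
  disc <- lapply(table[features], discretize_ew, bins = bins)
  cls <- as.integer(factor(table[[class_col]]))
  k <- length(features)
  su_class <- vapply(disc, symmetrical_uncertainty, numeric(1), y = cls)
  su_ff <- matrix(0, k, k, dimnames = list(features, features))
  if (k > 1L) for (i in 1:(k - 1L)) for (j in (i + 1L):k) {
    su_ff[i, j] <- su_ff[j, i] <- symmetrical_uncertainty(disc[[i]], disc[[j]])
  }
  list(features = features, su_class = su_class, su_ff = su_ff)
}

merit_from_cache <- function(cache, idx) {
  k <- length(idx)
  if (k == 0L) return(0)
  rcf <- mean(cache$su_class[idx])
  if (k == 1L) return(rcf)
  rff <- mean(cache$su_ff[idx, idx][upper.tri(diag(k))])
  denom <- sqrt(k + k * (k - 1) * rff)
  if (denom == 0) return(0)
  k * rcf / denom
}

#' CFS merit of a feature subset
#'
#' `merit = k * rcf / sqrt(k + k (k - 1) * rff)` where `rcf` is the
#' mean feature-class symmetrical uncertainty and `rff` the mean
#' pairwise feature-feature symmetrical uncertainty, both computed
#' after equal-width discretization into `bins` bins.  High-merit
#' subsets predict the class well while being mutually non-redundant.
#' The empty subset has merit 0 by convention.
#'
#' @param table Data frame with the features and the class column.
#' @param subset Character vector of feature names (possibly empty).
#' @param class_col Name of the class column (default `"activity"`).
#' @param bins Number of discretization bins (default 10).
#' @return The merit score.
#' @export
cfs_merit <- function(table, subset, class_col = "activity", bins = 10L) {
  if (nrow(table) == 0L) stop("empty table")
  unknown <- setdiff(subset, names(table))
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "))
  if (length(subset) == 0L) return(0)
  cache <- cfs_cache(table, subset, class_col, bins)
  merit_from_cache(cache, seq_along(subset))
}

#' Best-first CFS feature selection
#'
#' Forward best-first search over feature subsets maximizing the CFS
#' merit.  Starting from the empty set, the search repeatedly expands
#' the best unexpanded subset by one feature; it stops after
#' `non_improving_limit` consecutive expansions that fail to improve
#' the best merit seen (5 expansions, mirroring the usual forward /
#' termination-5 configuration of Weka's BestFirst).  Ties are broken
#' by schema order, so selection is deterministic.
#'
#' @param table Data frame with features and class.
#' @param features Candidate feature names (default: the 51 window
#'   features present in the table).
#' @param class_col Class column name.
#' @param non_improving_limit Stagnation limit (default 5).
#' @param bins Discretization bins.
#' @return Character vector of selected feature names (schema order).
#' @export
best_first_select <- function(table, features = NULL,
                              class_col = "activity",
                              non_improving_limit = 5L, bins = 10L) {
  if (is.null(features))
    features <- intersect(feature_names(), names(table))
  if (length(features) < 2L) stop("need at least 2 candidate features")
  cache <- cfs_cache(table, features, class_col, bins)
  k <- length(features)

  key <- function(idx) paste0("k", paste(sort(idx), collapse = ","))
  seen <- new.env(hash = TRUE, parent = emptyenv())
  open_sets <- list(integer(0))
  open_merit <- 0
  assign(key(integer(0)), TRUE, envir = seen)
  best_idx <- integer(0)
  best_merit <- 0
  stale <- 0L
  eps <- 1e-10

  while (length(open_sets) > 0L && stale < non_improving_limit) {
    i_best <- which.max(open_merit)  # first max: deterministic tie-break
    cur <- open_sets[[i_best]]
    open_sets <- open_sets[-i_best]
    open_merit <- open_merit[-i_best]

    improved <- FALSE
    for (f in setdiff(seq_len(k), cur)) {
      child <- c(cur, f)
      ck <- key(child)
      if (exists(ck, envir = seen, inherits = FALSE)) next
      assign(ck, TRUE, envir = seen)
      m <- merit_from_cache(cache, child)
      open_sets[[length(open_sets) + 1L]] <- child
      open_merit <- c(open_merit, m)
      if (m > best_merit + eps) {
        best_merit <- m
        best_idx <- child
        improved <- TRUE
      }
    }
    stale <- if (improved) 0L else stale + 1L
  }
  features[sort(best_idx)]
}
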