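#' Fit a Mahalanobis-distance model
#'
#' Estimates the mean vector and sample covariance (n-1 divisor) of an
#' observation matrix.  A numerically singular covariance gets a small
#' ridge `1e-8 * trace(V)/p` on its diagonal (with an absolute
#' fallback when the trace itself is zero) and a warning; distances are
#' then still defined, and identical rows all sit at distance zero.
#'
#' @param X Numeric n x p matrix (or data frame) with n >= p + 1.
#' @return An `md_model`: list with `mu`, `V`, `n`, `p` and the
#'   `ridge` that was applied (0 when none).
#' @export
fit_md_model <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X); p <- ncol(X)
  if (any(!is.finite(X))) stop("observation matrix contains non-finite values")
  if (n <= p) stop("insufficient observations for covariance (n = ", n,
                   ", p = ", p, ")")
  mu <- colMeans(X)
  V <- stats::cov(X)
  ridge <- 0
  ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev, 0) * 1e-10) {
    ridge <- 1e-8 * sum(diag(V)) / p
    if (ridge <= 0) ridge <- 1e-8
    V <- V + diag(ridge, p)
    warning("covariance numerically singular; ridge ", signif(ridge, 3),
            " added to the diagonal")
  }
  structure(list(mu = mu, V = V, n = n, p = p, ridge = ridge),
            class = "md_model")
}

#' Mahalanobis distances of observations from a fitted model
#'
#' Computes `Mi = sqrt((Xi - mu)' V^{-1} (Xi - mu))` for each row,
#' via a linear solve (no explicit matrix inversion).
#'
#' @param X Numeric matrix with `model$p` columns.
#' @param model An `md_model` from [fit_md_model()].
#' @return Numeric vector of distances (>= 0), one per row of `X`.
#' @export
mahalanobis_distances <- function(X, model) {
  stopifnot(inherits(model, "md_model"))
  X <- as.matrix(X)
  if (ncol(X) != model$p)
    stop("dimension mismatch: X has ", ncol(X), " columns, model expects ",
         model$p)
  Xc <- sweep(X, 2L, model$mu)
  sol <- solve(model$V, t(Xc))
  sqrt(pmax(colSums(t(Xc) * sol), 0))
}

#' Chi-square outlier threshold
#'
#' The squared Mahalanobis distance of a p-variate normal observation
#' is asymptotically chi-square with p degrees of freedom, so an
#' observation is flagged when `Mi^2` exceeds the (1 - alpha) quantile.
#'
#' @param alpha Significance level in (0, 1).
#' @param p Degrees of freedom (number of variables, >= 1).
#' @return The threshold on the squared distance.
#' @export
chi_square_cutoff <- function(alpha, p) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("`alpha` must be a single value in (0, 1)")
  if (p < 1) stop("`p` must be >= 1")
  stats::qchisq(1 - alpha, df = p)
}

#' Cleansing configuration
#'
#' @param alpha_stage1,alpha_stage2 Significance levels in (0, 1) for
#'   the within-recording and the per-activity-aggregate stage
#'   (defaults 0.05 and 0.01, i.e. 95% and 99% confidence).
#' @param md_features Feature columns used for the distance.  The
#'   default is the three windowed mean accelerations, matching the
#'   method's literal description; any subset of the 51 features can be
#'   supplied instead.
#' @return A `cleansing_config`.
#' @export
cleansing_config <- function(alpha_stage1 = 0.05, alpha_stage2 = 0.01,
                             md_features = c("mean_x", "mean_y", "mean_z")) {
  for (a in c(alpha_stage1, alpha_stage2))
    if (a <= 0 || a >= 1) stop("significance levels must be in (0, 1)")
  if (!length(md_features)) stop("`md_features` must be non-empty")
  structure(list(alpha_stage1 = alpha_stage1, alpha_stage2 = alpha_stage2,
                 md_features = md_features),
            class = "cleansing_config")
}

#' The four standard cleansing levels
#'
#' Confidence-level pairs for the two stages, written
#' `<stage1>_<stage2>`: `95_95`, `95_99`, `99_95`, `99_99` (95%
#' confidence corresponds to alpha 0.05, 99% to alpha 0.01).
#'
#' @param md_features Passed through to [cleansing_config()].
#' @return Named list of `cleansing_config` objects.
#' @export
cleansing_levels <- function(md_features = c("mean_x", "mean_y", "mean_z")) {
  a <- c("95" = 0.05, "99" = 0.01)
  out <- list()
  for (l1 in names(a)) for (l2 in names(a))
    out[[paste(l1, l2, sep = "_")]] <-
      cleansing_config(a[[l1]], a[[l2]], md_features)
  out
}

#' Flag multivariate outliers in one table
#'
#' Fits the Mahalanobis model on the table's `md_features` columns and
#' removes every row whose squared distance exceeds the chi-square
#' cutoff at `alpha`.  Single pass: the model is not refit after
#' removal.  Groups too small to estimate a covariance (fewer than
#' p + 2 rows) pass through unflagged with a warning instead of
#' aborting a many-file run.
#'
#' @param table Data frame containing the `md_features` columns.
#' @param md_features Character vector of column names.
#' @param alpha Significance level in (0, 1).
#' @param group Label recorded in the report.
#' @return List with `kept` (the surviving rows) and `report` (one row
#'   per input row: `group`, `row_id`, `md`, `threshold`, `flagged`).
#' @export
flag_outliers <- function(table, md_features, alpha, group = "all") {
  missing <- setdiff(md_features, names(table))
  if (length(missing))
    stop("md_features not in table: ", paste(missing, collapse = ", "))
  n <- nrow(table)
  p <- length(md_features)
  row_id <- if (".row_id" %in% names(table)) table$.row_id else seq_len(n)
  if (n < p + 2L) {
    warning("group '", group, "' has only ", n,
            " rows for p = ", p, "; passed through unflagged")
    report <- data.frame(group = group, row_id = row_id, md = NA_real_,
                         threshold = NA_real_, flagged = FALSE,
                         stringsAsFactors = FALSE)
    return(list(kept = table, report = report))
  }
  model <- fit_md_model(table[, md_features, drop = FALSE])
  md <- mahalanobis_distances(table[, md_features, drop = FALSE], model)
  cutoff <- chi_square_cutoff(alpha, p)
  flagged <- md^2 > cutoff
  report <- data.frame(group = group, row_id = row_id, md = md,
                       threshold = cutoff, flagged = flagged,
                       stringsAsFactors = FALSE)
  list(kept = table[!flagged, , drop = FALSE], report = report)
}

#' Two-stage Mahalanobis cleansing
#'
#' Stage 1 flags outliers independently within each subject x activity
#' table (each "file") at `alpha_stage1`; the survivors are then
#' compiled per activity and stage 2 flags outliers within each
#' activity aggregate at `alpha_stage2`, refitting the mean and
#' covariance on the compiled data.  Cleansing is pure row filtering:
#' surviving rows are returned unchanged.
#'
#' @param table A feature table with `subject` and `activity` columns.
#' @param config A [cleansing_config()].
#' @return A `cleansing_result`: list with `cleaned` (the surviving
#'   table), `stage1_report`, `stage2_report`, and the kept fractions
#'   `kept_stage1`, `kept_stage2` (relative to each stage's input).
#' @export
two_stage_clean <- function(table, config = cleansing_config()) {
  stopifnot(inherits(config, "cleansing_config"))
  if (!all(c("subject", "activity") %in% names(table)))
    stop("table must carry subject and activity columns")
  n0 <- nrow(table)
  if (n0 == 0L) stop("empty feature table")
  had_id <- ".row_id" %in% names(table)
  if (!had_id) table$.row_id <- seq_len(n0)

  g1 <- interaction(table$subject, table$activity, drop = TRUE)
  s1 <- lapply(levels(g1), function(g) {
    flag_outliers(table[g1 == g, , drop = FALSE], config$md_features,
                  config$alpha_stage1, group = g)
  })
  kept1 <- do.call(rbind, lapply(s1, `[[`, "kept"))
  report1 <- do.call(rbind, lapply(s1, `[[`, "report"))
  report1$stage <- 1L

  g2 <- factor(kept1$activity)
  s2 <- lapply(levels(g2), function(g) {
    flag_outliers(kept1[g2 == g, , drop = FALSE], config$md_features,
                  config$alpha_stage2, group = g)
  })
  cleaned <- do.call(rbind, lapply(s2, `[[`, "kept"))
  report2 <- do.call(rbind, lapply(s2, `[[`, "report"))
  report2$stage <- 2L
  rownames(cleaned) <- NULL

  res <- list(cleaned = cleaned,
              stage1_report = report1, stage2_report = report2,
              kept_stage1 = nrow(kept1) / n0,
              kept_stage2 = if (nrow(kept1)) nrow(cleaned) / nrow(kept1) else NA_real_)
  if (!had_id) res$cleaned$.row_id <- NULL
  structure(res, class = "cleansing_result")
}

#' @export
print.cleansing_result <- function(x, ...) {
  cat("Two-stage Mahalanobis cleansing\n",
      sprintf("  stage 1 kept: %.1f%%\n", 100 * x$kept_stage1),
      sprintf("  stage 2 kept: %.1f%% (of stage-1 survivors)\n",
              100 * x$kept_stage2),
      sprintf("  rows surviving: %d\n", nrow(x$cleaned)), sep = "")
  invisible(x)
}
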