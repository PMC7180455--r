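#' Summarize repeated F-measures for one model
#'
#' Mean, standard deviation (n-1 divisor) and the Anderson-Darling
#' composite-normality p-value (mean and variance estimated from the
#' sample) of a vector of per-repetition F-measures.  A constant
#' sample has no defined normality test; it is reported as degenerate
#' (`ad_p = NA`) rather than raising an error.
#'
#' @param x Numeric vector of at least 5 observations.
#' @return List with `mean`, `sd`, `ad_p`, `degenerate`.
#' @export
summarize_model <- function(x) {
  if (length(x) < 5L) stop("need at least 5 observations")
  s <- stats::sd(x)
  if (s == 0)
    return(list(mean = mean(x), sd = 0, ad_p = NA_real_, degenerate = TRUE))
  ad_p <- if (length(x) >= 8L) nortest::ad.test(x)$p.value else NA_real_
  list(mean = mean(x), sd = s, ad_p = ad_p, degenerate = FALSE)
}

#' Two-sample t-test p-value
#'
#' Welch (unequal-variance) by default; set `pooled = TRUE` for the
#' classical equal-variance test.  Two identical constant samples give
#' t = 0, p = 1; constant samples with different means give p = 0.
#'
#' @param a,b Numeric samples, each with >= 2 observations.
#' @param pooled Use the pooled-variance test.
#' @param alternative `"two.sided"` (default), `"greater"` or
#'   `"less"`; use a one-sided alternative when the hypothesis under
#'   assessment is directional.
#' @return The p-value.
#' @export
f_t_test <- function(a, b, pooled = FALSE,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b, var.equal = pooled,
                alternative = alternative)$p.value
}

#' One-way ANOVA p-value
#'
#' Classical fixed-effects one-way ANOVA F-test across groups.  When
#' every group has the same mean and there is within-group variation,
#' F = 0 and p = 1; with two groups the test is identical to the
#' pooled t-test (F = t^2).
#'
#' @param groups List of numeric vectors, >= 2 groups of >= 2
#'   observations each.
#' @return The p-value.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need at least 2 groups")
  if (any(lengths(groups) < 2L))
    stop("each group needs at least 2 observations")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::sd(y) == 0) return(1)
  stats::oneway.test(y ~ g, var.equal = TRUE)$p.value
}

#' Pairwise t-test p-value matrix
#'
#' @param models Named list of numeric F-measure vectors.
#' @param pooled Passed to [f_t_test()].
#' @return Symmetric matrix of p-values (diagonal `NA`).
#' @export
pairwise_t_matrix <- function(models, pooled = FALSE) {
  k <- length(models)
  out <- matrix(NA_real_, k, k, dimnames = list(names(models), names(models)))
  if (k > 1L) for (i in 1:(k - 1L)) for (j in (i + 1L):k)
    out[i, j] <- out[j, i] <- f_t_test(models[[i]], models[[j]], pooled)
  out
}

#' Statistical summary of an experiment
#'
#' For every classifier x test-kind cell: per-condition mean, SD and
#' Anderson-Darling normality p over the repetitions; the pairwise
#' t-test matrix across conditions; and the one-way ANOVA p-value
#' across the four cleaned conditions (the raw condition excluded, as
#' the ANOVA asks whether cleansing *level* matters).
#'
#' @param experiment A `har_experiment` from [run_experiment()].
#' @param pooled Use pooled-variance t-tests (default Welch).
#' @return A `stat_summary`: nested list keyed by
#'   `<classifier>.<test_kind>` with elements `summary` (data frame),
#'   `t_matrix` and `anova_p`.
#' @export
summarize_experiment <- function(experiment, pooled = FALSE) {
  stopifnot(inherits(experiment, "har_experiment"))
  res <- experiment$results
  out <- list()
  cleaned_conds <- c("95_95", "95_99", "99_95", "99_99")
  for (clf in unique(res$classifier)) {
    for (kind in unique(res$test_kind)) {
      sub <- res[res$classifier == clf & res$test_kind == kind, ]
      if (!nrow(sub)) next
      conds <- unique(sub$condition)
      samples <- lapply(conds, function(cd)
        sub$f_measure[sub$condition == cd])
      names(samples) <- conds
      summ <- do.call(rbind, lapply(conds, function(cd) {
        s <- summarize_model(samples[[cd]])
        data.frame(condition = cd, mean = s$mean, sd = s$sd, ad_p = s$ad_p,
                   stringsAsFactors = FALSE)
      }))
      have_cleaned <- intersect(cleaned_conds, conds)
      anova_p <- if (length(have_cleaned) >= 2L)
        one_way_anova(samples[have_cleaned]) else NA_real_
      out[[paste(clf, kind, sep = ".")]] <- list(
        summary = summ,
        t_matrix = pairwise_t_matrix(samples, pooled),
        anova_p = anova_p)
    }
  }
  structure(out, class = "stat_summary")
}

#' Write the experiment report files
#'
#' Emits, per classifier and test kind: the repetition x condition
#' F-measure table, the mean/SD/normality summary, and the pairwise
#' t-test matrix; plus `anova.csv` with the per-classifier ANOVA
#' p-values across cleaned conditions and a plain-text `summary.txt`
#' listing which pairwise comparisons are significant at `alpha`.
#' Regeneration from the same inputs is byte-identical.
#'
#' @param experiment A `har_experiment`.
#' @param stat_summary A `stat_summary` from [summarize_experiment()];
#'   computed if missing.
#' @param out_dir Output directory (created if needed).
#' @param alpha Significance level for the text summary (default 0.01).
#' @return Invisibly, the paths written.
#' @export
render_report <- function(experiment, stat_summary = NULL, out_dir,
                          alpha = 0.01) {
  stopifnot(inherits(experiment, "har_experiment"))
  if (!nrow(experiment$results)) stop("empty experiment results")
  if (is.null(stat_summary)) stat_summary <- summarize_experiment(experiment)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- character(0)
  res <- experiment$results

  for (key in names(stat_summary)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    clf <- parts[1L]; kind <- parts[2L]
    sub <- res[res$classifier == clf & res$test_kind == kind, ]
    wide <- stats::reshape(
      sub[, c("repetition", "condition", "f_measure")],
      idvar = "repetition", timevar = "condition", direction = "wide")
    names(wide) <- sub("^f_measure\\.", "", names(wide))
    wide <- wide[order(wide$repetition), , drop = FALSE]
    p1 <- file.path(out_dir, sprintf("f_by_condition_%s_%s.csv", clf, kind))
    utils::write.csv(wide, p1, row.names = FALSE, quote = FALSE)
    p2 <- file.path(out_dir, sprintf("summary_%s_%s.csv", clf, kind))
    utils::write.csv(stat_summary[[key]]$summary, p2,
                     row.names = FALSE, quote = FALSE)
    p3 <- file.path(out_dir, sprintf("t_tests_%s_%s.csv", clf, kind))
    utils::write.csv(stat_summary[[key]]$t_matrix, p3, quote = FALSE)
    paths <- c(paths, p1, p2, p3)
  }

  anova_df <- do.call(rbind, lapply(names(stat_summary), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1L]]
    data.frame(classifier = parts[1L], test_kind = parts[2L],
               anova_p = stat_summary[[key]]$anova_p,
               stringsAsFactors = FALSE)
  }))
  pa <- file.path(out_dir, "anova.csv")
  utils::write.csv(anova_df, pa, row.names = FALSE, quote = FALSE)
  paths <- c(paths, pa)

  lines <- c("Pairwise comparisons significant at alpha = " %+% alpha, "")
  for (key in names(stat_summary)) {
    tm <- stat_summary[[key]]$t_matrix
    cn <- colnames(tm)
    for (i in seq_len(nrow(tm))) for (j in seq_len(ncol(tm))) {
      if (j <= i || is.na(tm[i, j])) next
      verdict <- if (tm[i, j] < alpha) "DIFFER" else "similar"
      lines <- c(lines, sprintf("%s: %s vs %s  p = %.4f  -> %s",
                                key, cn[i], cn[j], tm[i, j], verdict))
    }
  }
  pt <- file.path(out_dir, "summary.txt")
  writeLines(lines, pt)
  invisible(c(paths, pt))
}

`%+%` <- function(a, b) paste0(a, b)
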