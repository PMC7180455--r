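#' Repeated split / cleanse / select / classify experiment
#'
#' The full evaluation protocol.  For each repetition the windowed
#' feature table is split per recording into set 1 (66%, development)
#' and set 2 (34%, raw held-out).  For each condition — `raw` or one of
#' the four two-stage cleansing levels — set 1 is cleansed accordingly,
#' a feature subset is chosen on the cleansed set 1 by best-first CFS,
#' and a KNN and a random-forest model are trained on it.  Each model
#' is evaluated three ways: 10-fold cross-validation within set 1
#' (optional), against set 2 cleansed at the matched level, and against
#' the untouched raw set 2.  Set 2 itself is never used for cleansing
#' decisions, feature selection or training, so the raw-unseen estimate
#' is leak-free.
#'
#' With the defaults (10 repetitions, 5 conditions, 2 classifiers) the
#' run instantiates exactly 100 trained models.
#'
#' @param table A feature table from [build_feature_table()].
#' @param conditions Subset of `c("raw", "95_95", "95_99", "99_95",
#'   "99_99")`.
#' @param repetitions Number of random splits (default 10).
#' @param seed Integer master seed.
#' @param classifiers Subset of `c("knn", "random_forest")`.
#' @param md_features Columns used for the Mahalanobis distance.
#' @param cv If `TRUE` (default) also run the within-set-1 10-fold
#'   cross-validation for every model.
#' @param train_fraction Set-1 share (default 0.66).
#'
#' @return A `har_experiment`: list with `results` (one row per
#'   repetition x condition x classifier x test kind, columns
#'   `repetition`, `condition`, `classifier`, `test_kind` in
#'   `c("cv", "cleaned_matched", "raw_unseen")`, `f_measure`,
#'   `n_train`, `n_test`, `kept_stage1`, `kept_stage2`), `n_models`,
#'   and `selected` (features chosen per repetition x condition).
#' @export
run_experiment <- function(table,
                           conditions = c("raw", "95_95", "95_99",
                                          "99_95", "99_99"),
                           repetitions = 10L, seed = 1L,
                           classifiers = c("knn", "random_forest"),
                           md_features = c("mean_x", "mean_y", "mean_z"),
                           cv = TRUE, train_fraction = 0.66) {
  check_feature_table(table)
  bad <- setdiff(conditions, c("raw", "95_95", "95_99", "99_95", "99_99"))
  if (length(bad)) stop("unknown condition(s): ", paste(bad, collapse = ", "))
  levels_cfg <- cleansing_levels(md_features)
  results <- list()
  selected <- list()
  n_models <- 0L

  for (r in seq_len(repetitions)) {
    rep_seed <- derive_seed(seed, r, 0L)
    plan <- split_dataset(table, train_fraction, seed = rep_seed)
    stopifnot(length(intersect(plan$train, plan$test)) == 0L)
    set1 <- table[plan$train, , drop = FALSE]
    set2 <- table[plan$test, , drop = FALSE]

    for (cond in conditions) {
      if (cond == "raw") {
        train_c <- set1
        test_matched <- set2
        kept1 <- 1; kept2 <- 1
      } else {
        cfg <- levels_cfg[[cond]]
        cr_train <- two_stage_clean(set1, cfg)
        cr_test <- two_stage_clean(set2, cfg)
        train_c <- cr_train$cleaned
        test_matched <- cr_test$cleaned
        kept1 <- cr_train$kept_stage1
        kept2 <- cr_train$kept_stage2
      }
      feats <- best_first_select(train_c, class_col = "activity")
      if (length(feats) < 1L) feats <- feature_names()
      selected[[paste0("rep", r, "_", cond)]] <- feats

      for (clf in classifiers) {
        model <- train_classifier(clf, train_c, feats,
                                  seed = derive_seed(rep_seed, cond_index(cond),
                                                     clf_index(clf)))
        n_models <- n_models + 1L
        evals <- list(
          cleaned_matched = test_matched,
          raw_unseen = set2)
        for (kind in names(evals)) {
          te <- evals[[kind]]
          cm <- confusion_matrix(te$activity, predict_classifier(model, te),
                                 levels = sort(unique(table$activity)))
          results[[length(results) + 1L]] <- data.frame(
            repetition = r, condition = cond, classifier = clf,
            test_kind = kind, f_measure = weighted_f_measure(cm),
            n_train = nrow(train_c), n_test = nrow(te),
            kept_stage1 = kept1, kept_stage2 = kept2,
            stringsAsFactors = FALSE)
        }
        if (cv) {
          cvr <- cross_validate(train_c, clf, feats,
                                seed = derive_seed(rep_seed, 99L,
                                                   clf_index(clf)))
          results[[length(results) + 1L]] <- data.frame(
            repetition = r, condition = cond, classifier = clf,
            test_kind = "cv", f_measure = cvr$f_measure,
            n_train = nrow(train_c), n_test = nrow(train_c),
            kept_stage1 = kept1, kept_stage2 = kept2,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(results = do.call(rbind, results), n_models = n_models,
                 selected = selected, seed = as.integer(seed)),
            class = "har_experiment")
}

cond_index <- function(cond)
  match(cond, c("raw", "95_95", "95_99", "99_95", "99_99"))
clf_index <- function(clf) match(clf, c("knn", "random_forest"))

#' @export
print.har_experiment <- function(x, ...) {
  cat("HAR cleansing experiment:", x$n_models, "trained models\n")
  agg <- stats::aggregate(f_measure ~ condition + classifier + test_kind,
                          data = x$results, FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
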