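#' Random per-recording train/test split
#'
#' Splits each subject x activity recording's windows into a training
#' share (set 1, default 66%) and a held-out raw test share (set 2,
#' 34%), so every recording contributes to both sets.  A recording
#' with a single window goes entirely to the training set with a
#' warning.  Deterministic given `seed`.
#'
#' @param table A feature table with `subject` and `activity` columns.
#' @param train_fraction Fraction of each recording's windows assigned
#'   to set 1 (default 0.66).
#' @param seed Integer seed.
#' @return A `split_plan`: list with integer row indices `train` and
#'   `test` (disjoint, exhaustive) and the `seed`.
#' @export
split_dataset <- function(table, train_fraction = 0.66, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("`train_fraction` must be in (0, 1)")
  set.seed(as.integer(seed))
  g <- interaction(table$subject, table$activity, drop = TRUE)
  train <- integer(0)
  test <- integer(0)
  for (lev in levels(g)) {
    idx <- which(g == lev)
    n <- length(idx)
    if (n < 2L) {
      warning("recording ", lev, " has a single window; assigned to train")
      train <- c(train, idx)
      next
    }
    n_train <- min(n - 1L, max(1L, round(train_fraction * n)))
    pick <- sample(idx, n_train)
    train <- c(train, pick)
    test <- c(test, setdiff(idx, pick))
  }
  structure(list(train = sort(train), test = sort(test),
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Train a KNN or random-forest classifier
#'
#' KNN stores the training data standardized to train-set mean and
#' standard deviation and classifies with k = 1 Euclidean nearest
#' neighbour (standardization is essential here: the 51 features mix
#' units and scales).  The random forest uses 100 trees with
#' `floor(sqrt(p))` candidate split variables.  Both are deterministic
#' given `seed`.
#'
#' @param kind `"knn"` or `"random_forest"`.
#' @param table Training feature table.
#' @param features Feature columns to use.
#' @param class_col Class column (default `"activity"`).
#' @param seed Integer seed.
#' @param k Neighbours for KNN (default 1).
#' @param ntree Trees for the random forest (default 100).
#' @return A `har_model`.
#' @export
train_classifier <- function(kind = c("knn", "random_forest"), table,
                             features, class_col = "activity", seed = 1L,
                             k = 1L, ntree = 100L) {
  kind <- match.arg(kind)
  if (nrow(table) == 0L) stop("empty training table")
  y <- factor(table[[class_col]])
  if (nlevels(y) < 2L) stop("training table contains a single class")
  X <- as.matrix(table[, features, drop = FALSE])
  centre <- colMeans(X)
  scale_ <- apply(X, 2L, stats::sd)
  scale_[scale_ == 0 | !is.finite(scale_)] <- 1
  Xs <- scale(X, center = centre, scale = scale_)

  fit <- NULL
  if (kind == "random_forest") {
    set.seed(as.integer(seed))
    fit <- randomForest::randomForest(
      x = as.data.frame(Xs), y = y, ntree = ntree,
      mtry = max(1L, floor(sqrt(length(features)))))
  }
  structure(list(kind = kind, features = features, class_col = class_col,
                 levels = levels(y), centre = centre, scale = scale_,
                 train_x = Xs, train_y = y, k = k, fit = fit,
                 seed = as.integer(seed)),
            class = "har_model")
}

#' Predict activity labels
#'
#' @param model A `har_model` from [train_classifier()].
#' @param table Feature table to classify.
#' @return Factor of predicted labels with the model's level set.
#' @export
predict_classifier <- function(model, table) {
  stopifnot(inherits(model, "har_model"))
  X <- as.matrix(table[, model$features, drop = FALSE])
  Xs <- scale(X, center = model$centre, scale = model$scale)
  if (model$kind == "knn") {
    factor(as.character(class::knn(model$train_x, Xs, model$train_y,
                                   k = model$k)),
           levels = model$levels)
  } else {
    factor(as.character(stats::predict(model$fit, as.data.frame(Xs))),
           levels = model$levels)
  }
}

#' Confusion matrix
#'
#' Rows are true classes, columns predicted classes, over the union of
#' levels present in either vector (or an explicit level set).
#'
#' @param truth,pred Label vectors of equal length.
#' @param levels Optional class level set.
#' @return A square contingency matrix.
#' @export
confusion_matrix <- function(truth, pred, levels = NULL) {
  if (is.null(levels))
    levels <- sort(unique(c(as.character(truth), as.character(pred))))
  table(factor(as.character(truth), levels = levels),
        factor(as.character(pred), levels = levels))
}

#' Support-weighted F-measure
#'
#' Per-class F1 = 2 P R / (P + R) (0 when P + R = 0, including classes
#' never predicted), averaged with weights proportional to each class's
#' true support — the averaging Weka reports as "weighted F-measure".
#'
#' @param cm Square confusion matrix (rows = truth, columns =
#'   predictions) with a positive total.
#' @return A value in \[0, 1\].
#' @export
weighted_f_measure <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  total <- sum(cm)
  if (total == 0) stop("confusion matrix is all zero")
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  sum(f1 * support) / total
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class; predictions are pooled into a single
#' confusion matrix whose weighted F-measure is returned.  Feature
#' selection is normally done once on the full table before calling
#' this (matching the evaluated protocol); pass `selector` to rerun
#' selection inside every training fold instead (the leakage-free
#' variant).
#'
#' @param table Feature table.
#' @param kind `"knn"` or `"random_forest"`.
#' @param features Feature columns.
#' @param class_col Class column.
#' @param folds Number of folds (default 10).
#' @param seed Integer seed.
#' @param selector Optional `function(train_table)` returning the
#'   feature names to use for that fold.
#' @return List with `f_measure` and the pooled `confusion`.
#' @export
cross_validate <- function(table, kind = c("knn", "random_forest"),
                           features, class_col = "activity", folds = 10L,
                           seed = 1L, selector = NULL) {
  kind <- match.arg(kind)
  n <- nrow(table)
  if (n < folds) stop("fewer rows (", n, ") than folds (", folds, ")")
  set.seed(as.integer(seed))
  y <- factor(table[[class_col]])
  fold_id <- integer(n)
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold_id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  levs <- levels(y)
  cm <- matrix(0, length(levs), length(levs), dimnames = list(levs, levs))
  for (f in seq_len(folds)) {
    tr <- table[fold_id != f, , drop = FALSE]
    te <- table[fold_id == f, , drop = FALSE]
    if (nrow(te) == 0L) next
    feats <- if (is.null(selector)) features else selector(tr)
    model <- train_classifier(kind, tr, feats, class_col,
                              seed = as.integer(seed) + f)
    pred <- predict_classifier(model, te)
    cm <- cm + unclass(confusion_matrix(te[[class_col]], pred, levels = levs))
  }
  list(f_measure = weighted_f_measure(cm), confusion = cm)
}
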