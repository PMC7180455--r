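test_that("per-recording splits partition windows near 66/34", {
  fx <- make_toy_recording_table()
  plan <- split_dataset(fx, seed = 5)
  expect_length(intersect(plan$train, plan$test), 0)
  expect_setequal(c(plan$train, plan$test), seq_len(nrow(fx)))
  g <- interaction(fx$subject, fx$activity, drop = TRUE)
  for (lev in levels(g)) {
    idx <- which(g == lev)
    n_tr <- sum(plan$train %in% idx)
    expect_lte(abs(n_tr - 0.66 * length(idx)), 1)
    expect_gt(n_tr, 0)
    expect_gt(sum(plan$test %in% idx), 0)
  }
  expect_identical(split_dataset(fx, seed = 5), plan)
  expect_false(identical(split_dataset(fx, seed = 6)$train, plan$train))

  one <- fx[c(1, which(fx$activity != fx$activity[1])[1:3]), ]
  expect_warning(p1 <- split_dataset(one, seed = 1), "single window")
  expect_true(1 %in% p1$train)
})

test_that("weighted F-measure matches hand arithmetic and conventions", {
  expect_equal(weighted_f_measure(diag(c(5, 3, 9))), 1)
  cm <- matrix(c(8, 3, 2, 7), 2, 2)  # rows truth, cols predicted
  expect_equal(weighted_f_measure(cm), 0.7493734, tolerance = 1e-6)
  # permutation equivariance in class order
  perm <- cm[c(2, 1), c(2, 1)]
  expect_equal(weighted_f_measure(perm), weighted_f_measure(cm))
  # class never predicted contributes F1 = 0, finite result
  cm3 <- matrix(c(5, 0, 0, 0, 0, 0, 0, 4, 6), 3, 3, byrow = TRUE)
  expect_lt(weighted_f_measure(cm3), 1)
  expect_gte(weighted_f_measure(cm3), 0)
  expect_error(weighted_f_measure(matrix(0, 2, 2)), "zero")
  expect_error(weighted_f_measure(matrix(1, 2, 3)), "square")
})

test_that("classifiers separate separable clusters and 1-NN memorizes", {
  set.seed(41)
  n <- 40
  tab <- data.frame(
    subject = "S1", activity = rep(c("a", "b"), each = n),
    window = seq_len(2 * n),
    f1 = c(rnorm(n, 0, 0.1), rnorm(n, 5, 0.1)),
    f2 = c(rnorm(n, 0, 0.1), rnorm(n, -5, 0.1)))
  for (clf in c("knn", "random_forest")) {
    m <- train_classifier(clf, tab, c("f1", "f2"), seed = 2)
    pred <- predict_classifier(m, tab)
    expect_equal(weighted_f_measure(confusion_matrix(tab$activity, pred)), 1)
  }
  # resubstitution: 1-NN returns each training point's own label
  noisy <- tab
  noisy$f1 <- rnorm(2 * n, 0, 3)
  m1 <- train_classifier("knn", noisy, c("f1", "f2"), seed = 2)
  expect_equal(as.character(predict_classifier(m1, noisy)), noisy$activity)

  expect_error(train_classifier("knn", tab[tab$activity == "a", ],
                                c("f1", "f2")), "single class")
})

test_that("random forest predictions are reproducible under a fixed seed", {
  fx <- make_toy_recording_table()
  m1 <- train_classifier("random_forest", fx, feature_names(), seed = 9)
  m2 <- train_classifier("random_forest", fx, feature_names(), seed = 9)
  expect_identical(predict_classifier(m1, fx), predict_classifier(m2, fx))
})

test_that("cross-validation folds cover rows disjointly and score sensibly", {
  set.seed(43)
  n <- 30
  tab <- data.frame(
    subject = "S1", activity = rep(c("a", "b", "c"), each = n),
    window = seq_len(3 * n),
    f1 = rep(c(0, 4, 8), each = n) + rnorm(3 * n, sd = 0.3),
    f2 = rep(c(0, -4, 4), each = n) + rnorm(3 * n, sd = 0.3))
  cvr <- cross_validate(tab, "knn", c("f1", "f2"), seed = 3)
  expect_equal(sum(cvr$confusion), nrow(tab))  # each row predicted once
  expect_gt(cvr$f_measure, 0.95)

  expect_error(cross_validate(tab[1:5, ], "knn", c("f1", "f2"), folds = 10),
               "fewer rows")
})

test_that("cross-validated F under permuted labels is near chance", {
  set.seed(44)
  C <- 4
  tab <- data.frame(subject = "S1",
                    activity = rep(letters[1:C], each = 30),
                    window = 1:120, f1 = rnorm(120), f2 = rnorm(120))
  fs <- replicate(5, {
    tab$activity <- sample(tab$activity)
    cross_validate(tab, "knn", c("f1", "f2"),
                   seed = sample.int(10000, 1))$f_measure
  })
  expect_lt(abs(mean(fs) - 1 / C), 0.1)
})
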