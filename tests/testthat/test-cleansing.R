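test_that("model fitting reproduces hand-computed moments", {
  X <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  m <- fit_md_model(X)
  expect_equal(unname(m$mu), c(1, 1))
  expect_equal(unname(m$V), matrix(c(4 / 3, 0, 0, 4 / 3), 2, 2))
  expect_equal(m$ridge, 0)

  # p = 1 reduces to univariate mean / variance
  x1 <- matrix(c(1, 2, 3, 4, 10), ncol = 1)
  m1 <- fit_md_model(x1)
  expect_equal(unname(m1$mu), 4)
  expect_equal(unname(drop(m1$V)), var(c(1, 2, 3, 4, 10)))

  expect_error(fit_md_model(matrix(rnorm(6), 2, 3)), "insufficient")
})

test_that("identical rows trigger the ridge path and zero distances", {
  X <- matrix(rep(c(1, 2, 3), each = 6), 6, 3)
  expect_warning(m <- fit_md_model(X), "singular")
  expect_gt(m$ridge, 0)
  d <- mahalanobis_distances(X, m)
  expect_equal(d, rep(0, 6))
})

test_that("distances match the explicit-inverse oracle and known values", {
  X <- rbind(c(0, 0), c(2, 0), c(0, 2), c(2, 2))
  m <- fit_md_model(X)
  d <- mahalanobis_distances(X, m)
  expect_equal(d[4], sqrt(1.5), tolerance = 1e-12)
  expect_equal(mahalanobis_distances(matrix(c(1, 1), 1, 2), m), 0)

  # identity covariance reduces to Euclidean distance
  set.seed(2)
  Z <- rbind(diag(3) * 4, -diag(3) * 4, matrix(rnorm(300), 100, 3))
  mz <- list(mu = c(0, 0, 0), V = diag(3), n = 106, p = 3, ridge = 0)
  class(mz) <- "md_model"
  expect_equal(mahalanobis_distances(Z, mz), sqrt(rowSums(Z^2)))

  # cross-check against both the loop oracle and stats::mahalanobis
  set.seed(3)
  X2 <- matrix(rnorm(200), 50, 4)
  m2 <- fit_md_model(X2)
  d2 <- mahalanobis_distances(X2, m2)
  expect_equal(d2, oracle_mahalanobis(X2), tolerance = 1e-9)
  expect_equal(d2^2, unname(stats::mahalanobis(X2, colMeans(X2), cov(X2))),
               tolerance = 1e-9)

  expect_error(mahalanobis_distances(matrix(1, 1, 3), m), "mismatch")
})

test_that("sum of squared distances equals (n-1) * p", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:100, 1)
    p <- sample(1:5, 1)
    if (n <= p + 1) n <- p + 5
    X <- matrix(rnorm(n * p, sd = runif(1, 0.5, 3)), n, p)
    m <- fit_md_model(X)
    d <- mahalanobis_distances(X, m)
    expect_equal(sum(d^2), (n - 1) * p, tolerance = 1e-8)
  }
})

test_that("distances are affine invariant", {
  set.seed(12)
  X <- matrix(rnorm(300), 100, 3)
  A <- matrix(c(2, 0.5, 0, -1, 3, 0.2, 0.4, 0, 1.5), 3, 3)
  b <- c(10, -5, 2)
  Y <- X %*% A + matrix(b, 100, 3, byrow = TRUE)
  d1 <- mahalanobis_distances(X, fit_md_model(X))
  d2 <- mahalanobis_distances(Y, fit_md_model(Y))
  expect_equal(d1, d2, tolerance = 1e-6)
})

test_that("chi-square cutoffs match the reference quantiles", {
  expect_equal(chi_square_cutoff(0.05, 3), 7.814728, tolerance = 1e-6)
  expect_equal(chi_square_cutoff(0.01, 3), 11.344867, tolerance = 1e-6)
  expect_lt(chi_square_cutoff(1 - 1e-12, 3), 1e-3)
  expect_error(chi_square_cutoff(0, 3), "alpha")
  expect_error(chi_square_cutoff(1.5, 3), "alpha")
})

test_that("flagging calibrates to alpha on clean normal data", {
  set.seed(13)
  df <- as.data.frame(matrix(rnorm(60000), 20000, 3))
  names(df) <- c("a", "b", "c")
  fr5 <- mean(flag_outliers(df, c("a", "b", "c"), 0.05)$report$flagged)
  fr1 <- mean(flag_outliers(df, c("a", "b", "c"), 0.01)$report$flagged)
  expect_true(fr5 > 0.045 && fr5 < 0.055)
  expect_true(fr1 > 0.007 && fr1 < 0.013)
})

test_that("a gross outlier among clean points is flagged", {
  set.seed(14)
  df <- as.data.frame(matrix(rnorm(1500), 500, 3))
  names(df) <- c("a", "b", "c")
  df[500, ] <- c(10, 10, 10)
  out <- flag_outliers(df, c("a", "b", "c"), 0.05)
  expect_true(out$report$flagged[500])
  expect_false(500 %in% as.integer(rownames(out$kept)))
})

test_that("tiny groups pass through unflagged with a warning", {
  df <- data.frame(a = c(1, 2), b = c(2, 1), c = c(0, 0))
  expect_warning(out <- flag_outliers(df, c("a", "b", "c"), 0.05), "passed")
  expect_equal(nrow(out$kept), 2)
  expect_false(any(out$report$flagged))
})

test_that("two-stage cleansing is vacuous at alpha ~ 0 and filters rows only", {
  fx <- make_toy_recording_table()
  res <- two_stage_clean(fx, cleansing_config(1e-12, 1e-12))
  expect_equal(nrow(res$cleaned), nrow(fx))
  expect_equal(res$kept_stage1, 1)
  expect_equal(res$kept_stage2, 1)

  res2 <- two_stage_clean(fx, cleansing_config(0.05, 0.05))
  # cleansing never alters surviving rows
  fxk <- fx
  fxk$.row_id <- seq_len(nrow(fx))
  res3 <- two_stage_clean(fxk, cleansing_config(0.05, 0.05))
  surv <- res3$cleaned
  expect_equal(surv[, feature_names()],
               fx[surv$.row_id, feature_names()],
               ignore_attr = TRUE)
})

test_that("smaller stage-2 alpha keeps a superset of rows", {
  set.seed(15)
  for (i in 1:20) {
    n <- 60
    tab <- data.frame(
      subject = rep(c("S1", "S2"), each = n / 2),
      activity = "act",
      mean_x = rnorm(n) + ifelse(runif(n) < 0.1, 5, 0),
      mean_y = rnorm(n), mean_z = rnorm(n) + 9.8)
    tab$.row_id <- seq_len(n)
    k95 <- two_stage_clean(tab, cleansing_config(0.05, 0.05))$cleaned$.row_id
    k99 <- two_stage_clean(tab, cleansing_config(0.05, 0.01))$cleaned$.row_id
    expect_true(all(k95 %in% k99))
    k95b <- two_stage_clean(tab, cleansing_config(0.01, 0.05))$cleaned$.row_id
    k99b <- two_stage_clean(tab, cleansing_config(0.01, 0.01))$cleaned$.row_id
    expect_true(all(k95b %in% k99b))
  }
})
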