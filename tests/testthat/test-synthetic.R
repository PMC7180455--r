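test_that("recording length and degenerate limits are exact", {
  spec <- default_activities()[[1]]
  rec <- generate_recording(spec, duration_s = 120, rate_hz = 51.2, seed = 1)
  expect_equal(nrow(rec$samples), 6144)  # round(120 * 51.2)

  flat <- activity_spec("flat", offset = c(0, 0, 9.81), noise_sd = 0)
  rec2 <- generate_recording(flat, duration_s = 3, rate_hz = 1, seed = 1)
  expect_equal(nrow(rec2$samples), 3)
  expect_equal(unname(rec2$samples),
               matrix(rep(c(0, 0, 9.81), each = 3), 3, 3))

  expect_error(generate_recording(spec, duration_s = 0), "duration")
  expect_error(generate_recording(spec, rate_hz = -1), "rate")
})

test_that("generated noise reproduces the specified axis correlation", {
  C <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0.35, 0.2, 0.35, 1), 3, 3)
  spec <- activity_spec("corr", offset = c(0, 0, 0), noise_sd = 1,
                        axis_correlation = C)
  rec <- generate_recording(spec, duration_s = 2000, rate_hz = 5, seed = 7)
  emp <- cor(rec$samples)
  expect_lt(max(abs(emp - C)), 0.03)
})

test_that("identical plan and seed give identical output, on disk too", {
  plan <- dataset_plan(subjects = 2, activities = default_activities()[1:3],
                       duration_s = 5, seed = 11)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_dataset(plan, contamination_spec(), d1)
  generate_dataset(plan, contamination_spec(), d2)
  f1 <- list.files(d1)
  expect_length(f1, 6 + 2)  # 2 x 3 recordings + manifest + truth
  for (f in f1)
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("a plan with the study's per-activity file counts yields 423 files", {
  counts <- c(21, 25, 25, 23, 21, 25, 25, 24, 24, 23, 21, 23, 25, 23, 23,
              24, 23, 25)
  acts <- lapply(seq_along(counts), function(i)
    activity_spec(paste0("act", sprintf("%02d", i)),
                  offset = c(i %% 5, i %% 3, 9.8), noise_sd = 0.3))
  plan <- dataset_plan(subjects = counts, activities = acts,
                       duration_s = 0.5, rate_hz = 8, seed = 2)
  d <- withr::local_tempdir()
  manifest <- generate_dataset(plan, no_contamination(), d)
  expect_equal(nrow(manifest), 423)
  expect_length(list.files(d, pattern = "^S"), 423)
  on_disk <- utils::read.csv(file.path(d, "manifest.csv"))
  expect_equal(nrow(on_disk), 423)
})

test_that("realized contamination fraction behaves binomially", {
  spec <- activity_spec("c", offset = c(0, 0, 9.8), noise_sd = 0.3)
  eps <- 0.15
  n_seg_per_rec <- 30
  n_rec <- 40
  hits <- vapply(seq_len(n_rec), function(s) {
    rec <- generate_recording(spec, contamination_spec(rate = eps),
                              duration_s = n_seg_per_rec * 4, rate_hz = 10,
                              seed = 100 + s)
    length(rec$contaminated_segments)
  }, numeric(1))
  N <- n_seg_per_rec * n_rec
  frac <- sum(hits) / N
  expect_lt(abs(frac - eps), 3 * sqrt(eps * (1 - eps) / N))
})

test_that("clean stationary windows stay near the base offset", {
  # drift disabled: the bound concerns the stationary noise component
  spec <- activity_spec("s", offset = c(1, -2, 9.8), noise_sd = 0.5,
                        drift_sd = 0)
  rec <- generate_recording(spec, no_contamination(),
                            duration_s = 120, rate_hz = 51.2, seed = 3)
  wins <- window_recording(rec, 4)
  L <- nrow(wins[[1]]$samples)
  bound <- 5 * spec$noise_sd / sqrt(L)
  for (w in wins)
    expect_true(all(abs(colMeans(w$samples) - spec$offset) < bound))
})

test_that("edge artifacts replace the recording ends with a low ramp", {
  spec <- activity_spec("e", offset = c(0, 0, 9.8), noise_sd = 0.4)
  rec <- generate_recording(spec, contamination_spec(rate = 0,
                                                     edge_artifact_s = 10),
                            duration_s = 60, rate_hz = 10, seed = 5)
  head_z <- rec$samples[1:100, 3]
  # ramp rises from ~0 toward the offset
  expect_lt(mean(head_z[1:10]), 1)
  expect_gt(mean(head_z[91:100]), 8)
  # residual variation around the ramp is low compared with the body
  idx <- 1:100
  resid_head <- stats::residuals(stats::lm(head_z ~ idx))
  mid <- rec$samples[250:350, 3]
  resid_mid <- stats::residuals(stats::lm(mid ~ seq_along(mid)))
  expect_gt(stats::sd(resid_mid), stats::sd(resid_head))
})

test_that("specification constructors validate their invariants", {
  expect_error(activity_spec("x", offset = c(0, 0)), "offset")
  badC <- matrix(c(1, 0.9, 0.9, 1), 2, 2)
  expect_error(activity_spec("x", offset = c(0, 0, 9.8),
                             axis_correlation = badC))
  nonpd <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 1), 3, 3)
  expect_error(activity_spec("x", offset = c(0, 0, 9.8),
                             axis_correlation = nonpd), "positive definite")
  expect_error(contamination_spec(rate = 1.2), "rate")
  expect_error(contamination_spec(scale_inflation = 0.5), "scale_inflation")
  expect_error(dataset_plan(subjects = 0), "subjects")
})
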