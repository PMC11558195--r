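test_that("grid resampling interpolates linearly and reproduces raw samples", {
  s <- raw_stream("p1", "HR", c(0, 2), c(100, 104))
  tr <- resample_to_grid(s, horizon = 5L)
  expect_equal(tr$value[2L], 102)              # linear midpoint at minute 1
  expect_equal(tr$value[1L], 100)              # exact at raw sample times
  expect_equal(tr$value[3L], 104)
  expect_false(any(tr$valid[4:5]))             # beyond the last sample
  expect_error(resample_to_grid(raw_stream("p1", "HR", 1, 80), 5L),
               "insufficient", class = "spm_data_error")
})

test_that("minutes outside the first/last measurement are invalid", {
  t <- seq(60, 10020, by = 0.5)
  s <- raw_stream("p1", "SPO2", t, rep(98, length(t)))
  tr <- resample_to_grid(s, horizon = 10080L)
  expect_false(any(tr$valid[1:60]))            # minutes 0-59
  expect_false(any(tr$valid[10022:10080]))     # minutes 10021-10079
  expect_true(all(tr$valid[61:10021]))
})

test_that("dropout gaps are flagged inclusively at 3 minutes and never interpolated", {
  # 9 silent minutes between samples at t=0 and t=10
  s <- raw_stream("p1", "HR", c(0, 10), c(100, 120))
  g <- detect_dropouts(s, horizon = 12L)
  expect_equal(g$start, 1L)
  expect_equal(g$end, 10L)
  tr <- resample_to_grid(s, horizon = 12L)
  expect_false(any(tr$valid[2:10]))            # minutes 1-9 never bridged
  expect_true(tr$valid[1L] && tr$valid[11L])

  # exactly 3 silent minutes -> dropout (inclusive threshold)
  s3 <- raw_stream("p1", "HR", c(0, 0.5, 4.2, 5), c(1, 1, 2, 2))
  g3 <- detect_dropouts(s3, horizon = 6L)
  expect_equal(unlist(g3), c(start = 1L, end = 4L))
  expect_false(any(resample_to_grid(s3, 6L)$valid[2:4]))

  # 2 silent minutes -> interpolated across
  s2 <- raw_stream("p1", "HR", c(0, 3), c(100, 106))
  expect_equal(nrow(detect_dropouts(s2, horizon = 4L)), 0L)
  tr2 <- resample_to_grid(s2, horizon = 4L)
  expect_true(all(tr2$valid))
  expect_equal(tr2$value, c(100, 102, 104, 106))

  # dense sampling -> no dropouts; empty stream -> whole horizon
  dense <- raw_stream("p1", "HR", seq(0, 60, 0.5), rep(1, 121))
  expect_equal(nrow(detect_dropouts(dense, 61L)), 0L)
  empty <- raw_stream("p1", "HR", numeric(), numeric())
  expect_equal(unlist(detect_dropouts(empty, 61L)),
               c(start = 0L, end = 61L))
})

test_that("validity partitions the horizon into valid, dropout and edge gaps", {
  set.seed(9)
  t <- sort(c(runif(200, 10, 50), runif(200, 60, 115)))  # 10-min internal gap
  s <- raw_stream("p1", "HR", t, rnorm(400, 100))
  H <- 120L
  tr <- resample_to_grid(s, H)
  span <- seq.int(ceiling(min(t)), floor(max(t)))         # evaluated span
  pre_post <- setdiff(0:(H - 1L), span)
  dropout_minutes <- span[!tr$valid[span + 1L]]
  valid_minutes <- span[tr$valid[span + 1L]]
  expect_false(any(tr$valid[pre_post + 1L]))
  expect_setequal(c(valid_minutes, dropout_minutes, pre_post), 0:(H - 1L))
  expect_length(c(valid_minutes, dropout_minutes, pre_post), H)
})

test_that("the Hampel identifier flags a gross spike and replaces it by the window median", {
  set.seed(21)
  x <- rnorm(21)
  x[11L] <- 10
  h <- hampel_filter(x, window = 11L, alpha = 0.05)
  win <- x[6:16]                               # centered window, by hand
  med <- median(win)
  mad0 <- median(abs(win - med))
  expect_true(abs(x[11L] - med) > h$multiplier * 1.4826 * mad0)
  expect_true(h$flagged[11L])
  expect_identical(h$values[11L], med)
  expect_false(any(h$flagged[-11L]))

  const <- hampel_filter(rep(7, 50))           # MAD = 0: never flags
  expect_false(any(const$flagged))
  expect_identical(const$values, rep(7, 50))
})

test_that("threshold multipliers follow the allowed misidentification rate", {
  # asymptotic construction: z_{1-alpha/2} (x 1.4826 MAD scaling)
  expect_equal(hampel_threshold_multiplier(11L, 0.05, "asymptotic"),
               qnorm(0.975))
  expect_equal(qnorm(0.975) * 1.4826, 2.906, tolerance = 1e-3)
  # finite-sample multiplier exceeds it and is deterministic (cached)
  m1 <- hampel_threshold_multiplier(11L, 0.05)
  expect_gt(m1, qnorm(0.975))
  expect_identical(m1, hampel_threshold_multiplier(11L, 0.05))
  # tighter alpha -> larger multiplier
  expect_gt(hampel_threshold_multiplier(11L, 0.01), m1)
})

test_that("Hampel agrees with an independent implementation on valid series", {
  set.seed(2)
  x <- rnorm(500)
  x[c(50, 200, 321)] <- x[c(50, 200, 321)] + 8
  h <- hampel_filter(x)
  pr <- pracma::hampel(x, k = 5L, t0 = h$multiplier)
  core <- 6:495                                # identical away from edges
  expect_setequal(which(h$flagged), pr$ind)
  expect_equal(h$values[core], pr$y[core])
})

test_that("masked entries are excluded from window statistics", {
  set.seed(7)
  x <- rnorm(30)
  x[10L] <- 20
  x[15L] <- NA
  valid <- is.finite(x)
  h <- hampel_filter(x, valid, window = 11L)
  win <- x[setdiff(5:15, 15L)]                 # mask drops the NA entry
  expect_true(h$flagged[10L])
  expect_identical(h$values[10L], median(win))
  expect_false(any(h$flagged[!valid]))
  expect_true(is.na(h$values[15L]))            # invalid entries untouched
})

test_that("preprocess_patient cleans, reports, and respects exclusion", {
  co <- generate_cohort(default_template(), 2, horizon = 720L, seed = 31)
  pp <- preprocess_patient(co[[1L]]$streams, 720L)
  expect_false(pp$record$excluded)
  expect_equal(pp$report$n_dropout, 0L)
  # background flag rate on clean smooth data stays at or below ~alpha
  expect_gt(pp$report$outlier_fraction, 0)
  expect_lt(pp$report$outlier_fraction, 1.2 * 0.05)

  # injected spikes push the outlier fraction above the contamination rate
  tpl <- attr(co, "template")
  contaminated <- inject_missingness(co[[2L]]$streams, 0, 0.05,
                                     seed = 32, template = tpl)
  pc <- preprocess_patient(contaminated, 720L)
  expect_gte(pc$report$outlier_fraction, 0.05)

  # a fully silent signal yields an all-invalid trace and exclusion
  silent <- co[[1L]]$streams
  silent$SPO2 <- raw_stream("P001", "SPO2", numeric(), numeric())
  ps <- preprocess_patient(silent, 720L)
  expect_true(ps$record$excluded)
  expect_false(any(ps$record$traces$SPO2$valid))
})
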