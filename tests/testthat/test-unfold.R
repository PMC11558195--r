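test_that("the cohort tensor has patients x signals x minutes shape", {
  recs <- lapply(sprintf("p%02d", 1:14), make_record, horizon = 10080L)
  tz <- build_tensor(recs)
  expect_equal(dim(tz$data), c(14L, 5L, 10080L))
  expect_equal(dim(tz$valid), dim(tz$data))
  expect_equal(tz$signal_labels, SPM_SIGNALS)

  one <- build_tensor(list(make_record("solo", horizon = 12L)))
  expect_equal(dim(one$data), c(1L, 5L, 12L))

  holey <- make_record("h", horizon = 12L, invalid = list(HR = c(3L, 4L)))
  th <- build_tensor(list(holey))
  expect_false(any(th$valid[1L, 1L, 4:5]))
  expect_true(all(is.na(th$data[1L, 1L, 4:5])))

  expect_error(build_tensor(list(make_record("a", 10L),
                                 make_record("b", 12L))),
               "heterogeneous", class = "spm_contract_error")
})

test_that("lag augmentation triples the signal axis with adjacent lags", {
  recs <- make_varying_cohort(3, horizon = 20L, seed = 3)
  tz <- lag_augment(build_tensor(recs), 2L)
  expect_equal(dim(tz$data)[2L], 15L)
  expect_equal(tz$signal_labels[1:4],
               c("HR_lag0", "HR_lag1", "HR_lag2", "ABP_SYS_lag0"))
  # column (j, l) at minute k holds signal j at minute k - l
  base <- build_tensor(recs)
  expect_equal(tz$data[2L, 2L, 6L], base$data[2L, 1L, 5L])
  expect_equal(tz$data[2L, 3L, 6L], base$data[2L, 1L, 4L])
  # lag boundary: minutes k < l invalid
  expect_false(tz$valid[1L, 2L, 1L])
  expect_false(any(tz$valid[, 3L, 1:2]))
  # identity at zero lags; contract at absurd lags
  expect_identical(lag_augment(build_tensor(recs), 0L),
                   build_tensor(recs))
  expect_error(lag_augment(build_tensor(recs), 20L),
               class = "spm_contract_error")
})

test_that("batch-wise normalization is exact on training data and anchors SpO2", {
  recs <- make_varying_cohort(6, horizon = 30L, seed = 5)
  tz <- lag_augment(build_tensor(recs), 2L)
  model <- fit_normalization(tz)
  z <- apply_normalization(tz, model)
  uf <- variable_wise_unfold(z)

  # every non-SpO2 (column, minute) has cross-patient mean 0 and SD 1 exactly
  for (j in which(z$col_base != "SPO2")) {
    zz <- z$data[, j, , drop = TRUE]
    ok <- z$valid[, j, , drop = TRUE]
    zz[!ok] <- NA
    mcol <- colMeans(zz, na.rm = TRUE)
    scol <- apply(zz, 2L, sd, na.rm = TRUE)
    expect_lt(max(abs(mcol), na.rm = TRUE), 1e-12)
    expect_lt(max(abs(scol - 1), na.rm = TRUE), 1e-12)
  }
  # SpO2 uses the fixed anchor for every lag
  spo2_rows <- which(z$col_base == "SPO2")
  expect_true(all(model$mu[spo2_rows, ] == 100))
  expect_true(all(model$sigma[spo2_rows, ] == 5))

  # arithmetic of the anchor: 100% -> 0, 95% -> -1
  rec95 <- make_record("q", horizon = 30L,
                       levels = c(default_levels[1:4], SPO2 = 95))
  z95 <- apply_normalization(lag_augment(build_tensor(list(rec95)), 2L),
                             model)
  expect_equal(unique(as.vector(z95$data[1L, spo2_rows[1L], ])), -1)
  rec100 <- make_record("r", horizon = 30L,
                        levels = c(default_levels[1:4], SPO2 = 100))
  z100 <- apply_normalization(lag_augment(build_tensor(list(rec100)), 2L),
                              model)
  expect_equal(unique(as.vector(z100$data[1L, spo2_rows[1L], ])), 0)

  # normalization is invertible at valid cells
  back <- denormalize(z, model)
  expect_equal(back$data[tz$valid], tz$data[tz$valid], tolerance = 1e-12)
})

test_that("degenerate cells hit the SD floor or inherit nearest-minute statistics", {
  # all patients identical -> SD floored, never zero
  recs <- lapply(c("a", "b", "c"), make_record, horizon = 10L)
  model <- fit_normalization(build_tensor(recs))
  expect_true(all(model$sigma > 0))

  # a minute with <2 valid patients inherits from its nearest valid minute
  recs2 <- make_varying_cohort(3, horizon = 10L, seed = 8)
  recs2[[1L]] <- make_record("V01", 10L,
                             series = lapply(recs2[[1L]]$traces, `[[`,
                                             "value"),
                             invalid = list(HR = 4L))
  recs2[[2L]] <- make_record("V02", 10L,
                             series = lapply(recs2[[2L]]$traces, `[[`,
                                             "value"),
                             invalid = list(HR = 4L))
  m2 <- fit_normalization(build_tensor(recs2))
  expect_equal(m2$n_eff[1L, 5L], 1L)
  expect_equal(m2$mu[1L, 5L], m2$mu[1L, 4L])
  expect_equal(m2$sigma[1L, 5L], m2$sigma[1L, 4L])
})

test_that("variable-wise unfolding keeps complete rows and refolds exactly", {
  recs <- make_varying_cohort(2, horizon = 4L, seed = 13)
  z <- build_tensor(recs)
  uf <- variable_wise_unfold(z)
  expect_equal(dim(uf$X), c(8L, 5L))           # all (patient, minute) pairs
  expect_equal(uf$row_index$minute, rep(0:3, 2L))

  recs[[1L]] <- make_record("V01", 4L,
                            series = lapply(recs[[1L]]$traces, `[[`, "value"),
                            invalid = list(SPO2 = 1L))
  uf2 <- variable_wise_unfold(build_tensor(recs))
  expect_equal(nrow(uf2$X), 7L)                # the incomplete row dropped
  expect_false(any(uf2$row_index$minute[uf2$row_index$patient_id == "V01"]
                   == 1L))

  # refolding by row_index reproduces the tensor at complete rows
  folded <- fold_statistic(uf2$X[, 1L], uf2$row_index,
                           patient_ids = c("V01", "V02"), K = 4L)
  expect_equal(folded[2L, ], build_tensor(recs)$data[2L, 1L, ])
  expect_true(is.na(folded[1L, 2L]))
})

test_that("lagged columns of the unfolded matrix are shifted copies of lag 0", {
  recs <- make_varying_cohort(3, horizon = 25L, seed = 21)
  tz <- lag_augment(build_tensor(recs), 2L)
  z <- apply_normalization(tz, fit_normalization(tz))
  for (i in 1:3) {
    expect_equal(z$data[i, 2L, 3:25], z$data[i, 1L, 2:24])  # HR lag 1
    expect_equal(z$data[i, 3L, 3:25], z$data[i, 1L, 1:23])  # HR lag 2
  }
})

test_that("normalization models serialize and restore faithfully", {
  recs <- make_varying_cohort(4, horizon = 15L, seed = 2)
  tz <- lag_augment(build_tensor(recs), 1L)
  model <- fit_normalization(tz)
  path <- withr::local_tempfile(fileext = ".csv")
  write_normalization(model, path)
  back <- read_normalization(path)
  expect_identical(back$mu, unname(model$mu))
  expect_identical(back$sigma, unname(model$sigma))
  expect_equal(back$signal_labels, model$signal_labels)
})
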