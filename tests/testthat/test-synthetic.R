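test_that("the default template encodes the expected recovery shapes", {
  tpl <- default_template()
  # ABP dips in the first day and recovers: hour 12 below hour 72
  for (sig in c("ABP_SYS", "ABP_DIA", "ABP_MEAN"))
    expect_lt(template_baseline(tpl, sig, 720),
              template_baseline(tpl, sig, 4320))
  # SpO2 baseline is non-increasing over the week
  spo2 <- template_baseline(tpl, "SPO2", 0:10079)
  expect_true(all(diff(spo2) <= 0))
  expect_lte(max(spo2), 100)
  # all baselines finite and positive
  for (sig in SPM_SIGNALS)
    expect_true(all(is.finite(template_baseline(tpl, sig, 0:10079)) &
                      template_baseline(tpl, sig, 0:10079) > 0))
  # template validation rejects broken inputs
  bad <- tpl$signals
  bad$HR$sd_between <- -1
  expect_error(trajectory_template(bad, tpl$correlation),
               class = "spm_contract_error")
  expect_error(trajectory_template(tpl$signals, diag(5) * 0),
               class = "spm_contract_error")
})

test_that("generation is bit-identical under a fixed seed", {
  a <- generate_cohort(default_template(), 3, horizon = 90L, seed = 123)
  b <- generate_cohort(default_template(), 3, horizon = 90L, seed = 123)
  expect_identical(a[[2L]]$streams$HR$values, b[[2L]]$streams$HR$values)
  expect_identical(a[[3L]]$truth$grid, b[[3L]]$truth$grid)
  c_ <- generate_cohort(default_template(), 3, horizon = 90L, seed = 124)
  expect_false(identical(a[[1L]]$streams$HR$values,
                         c_[[1L]]$streams$HR$values))
})

test_that("cohort statistics recover the declared template parameters", {
  tpl <- default_template()
  H <- 120L
  co <- generate_cohort(tpl, 200, horizon = H, seed = 55)
  for (sig in c("HR", "ABP_MEAN", "SPO2")) {
    sp <- tpl$signals[[sig]]
    truth <- sapply(co, function(p) p$truth$grid[, sig])   # H x n
    base <- template_baseline(tpl, sig, 0:(H - 1L))
    dev <- rowMeans(truth) - base
    # cross-patient mean tracks the baseline within standard error
    se <- sqrt(sp$sd_between^2 + sp$sd_within^2) / sqrt(200)
    expect_lt(abs(mean(dev)), 4 * se)
    # cross-patient SD matches the declared total SD
    expect_equal(mean(apply(truth, 1L, sd)),
                 sqrt(sp$sd_between^2 + sp$sd_within^2),
                 tolerance = 0.1)
    # lag-1 autocorrelation of the within-patient residual ~ AR coefficient
    # (pooled, with the known zero mean, to avoid small-sample bias)
    offs <- sapply(co, function(p) p$truth$offsets[[sig]]) * sp$sd_between
    resid <- sweep(truth, 2L, offs) - base
    ac1 <- sum(resid[-1L, ] * resid[-H, ]) / sum(resid[-H, ]^2)
    expect_equal(ac1, sp$ar_coef, tolerance = 0.02)
  }
  # cross-signal correlation of the innovations matches the template
  innov <- do.call(rbind, lapply(co[1:100], function(p) {
    r <- sweep(p$truth$grid, 2L,
               p$truth$offsets * sapply(tpl$signals, `[[`, "sd_between"))
    r <- r - sapply(SPM_SIGNALS, function(s)
      template_baseline(tpl, s, 0:(H - 1L)))
    r[-1L, ] - 0.95^1 * r[-H, ]
  }))
  expect_equal(unname(cor(innov)), unname(tpl$correlation),
               tolerance = 0.07)
})

test_that("anomaly injection modifies exactly the requested windows", {
  tpl <- default_template()
  co <- generate_cohort(tpl, 2, horizon = 600L, seed = 9)
  streams <- co[[1L]]$streams
  expect_identical(inject(streams, list(), seed = 1, template = tpl),
                   streams)

  spec <- anomaly_spec("mean_shift", "ABP_DIA", 120, 360, magnitude = 3)
  shifted <- inject(streams, list(spec), seed = 1, template = tpl)
  sd_loc <- sqrt(tpl$signals$ABP_DIA$sd_between^2 +
                   tpl$signals$ABP_DIA$sd_within^2)
  win <- streams$ABP_DIA$times >= 120 & streams$ABP_DIA$times < 360
  expect_equal(shifted$ABP_DIA$values[win],
               streams$ABP_DIA$values[win] + 3 * sd_loc)
  expect_identical(shifted$ABP_DIA$values[!win],
                   streams$ABP_DIA$values[!win])
  expect_identical(shifted$HR$values, streams$HR$values)

  expect_error(inject(streams, list(spec,
                                    anomaly_spec("mean_shift", "ABP_DIA",
                                                 300, 400)),
                      seed = 1, template = tpl),
               "overlapping", class = "spm_contract_error")

  # spike train: every injected spike minute is flagged by the Hampel step
  spk <- anomaly_spec("spike_train", "HR", 60, 420, magnitude = 10)
  spiked <- inject(streams, list(spk), seed = 4, template = tpl)
  minutes <- attr(spiked, "injections")$HR
  expect_gte(length(minutes), 10L)
  tr <- resample_to_grid(spiked$HR, 600L)
  hf <- hampel_filter(tr$value, tr$valid)
  expect_true(all(hf$flagged[minutes + 1L]))
})

test_that("missingness injection hits the declared dropout regime", {
  tpl <- default_template()
  co <- generate_cohort(tpl, 2, horizon = 10080L, seed = 71)
  streams <- co[[1L]]$streams
  expect_identical(inject_missingness(streams, 0, 0, seed = 1,
                                      template = tpl), streams)
  out <- inject_missingness(streams, 0.0063, 0.0263, seed = 2,
                            template = tpl)
  book <- attr(out, "injections")
  pp <- preprocess_patient(out, 10080L)
  # every injected gap is >= 3 minutes by construction, so all are
  # detected: the dropout fraction is recovered within +-50% relative
  expect_gt(pp$report$dropout_fraction, 0.0063 * 0.5)
  expect_lt(pp$report$dropout_fraction, 0.0063 * 1.5)
  # injected spikes are recovered on top of the identifier's own
  # background rate on clean data (~alpha/2 on smooth series)
  flagged_hits <- vapply(SPM_SIGNALS, function(sig) {
    tr <- resample_to_grid(out[[sig]], 10080L)
    hf <- hampel_filter(tr$value, tr$valid)
    mins <- book[[sig]]$outlier_minutes
    mean(hf$flagged[mins + 1L])
  }, 0)
  expect_gt(mean(flagged_hits), 0.8)
  clean_bg <- preprocess_patient(streams, 10080L)$report$outlier_fraction
  expect_lte(pp$report$outlier_fraction, 0.0263 + 1.5 * clean_bg)
})
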