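# fixtures are built in code; nothing is read from disk

default_levels <- c(HR = 150, ABP_SYS = 75, ABP_DIA = 45, ABP_MEAN = 55,
                    SPO2 = 98)

# patient record with constant (or supplied) per-signal series;
# `invalid` is a named list of 0-based minutes to blank out
make_record <- function(pid, horizon = 60L, levels = default_levels,
                        series = NULL, invalid = list()) {
  traces <- lapply(SPM_SIGNALS, function(sig) {
    v <- if (!is.null(series)) series[[sig]] else rep(levels[[sig]], horizon)
    ok <- rep(TRUE, horizon)
    if (!is.null(invalid[[sig]])) {
      ok[invalid[[sig]] + 1L] <- FALSE
      v[invalid[[sig]] + 1L] <- NA_real_
    }
    signal_trace(pid, sig, v, ok)
  })
  patient_record(pid, setNames(traces, SPM_SIGNALS))
}

# cohort of records with cross-patient variation, built directly on the grid
make_varying_cohort <- function(n, horizon = 60L, seed = 1L, sd = 2) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    series <- lapply(setNames(SPM_SIGNALS, SPM_SIGNALS), function(sig)
      default_levels[[sig]] + rnorm(1, 0, sd) + rnorm(horizon, 0, sd / 2))
    make_record(sprintf("V%02d", i), horizon, series = series)
  })
}

# generated + preprocessed synthetic records
make_synth_records <- function(n, horizon, seed) {
  co <- generate_cohort(default_template(), n, horizon = horizon,
                        seed = seed)
  lapply(co, function(p) preprocess_patient(p$streams, horizon)$record)
}

# long-format gridded trace table for read_cohort()
write_trace_csv <- function(records, path) {
  write_cohort(records, path)
  path
}

rand_orthogonal <- function(J, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(rnorm(J * J), J, J)))
}
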