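#' Construct a trajectory template for the synthetic cohort generator
#'
#' A template declares, per base signal, the cohort baseline curve (piecewise
#' linear between knots over the 7-day grid), the between-patient SD, the
#' within-patient AR(1) noise model (coefficient at 1-minute lag and
#' stationary SD), and one cross-signal correlation matrix shared by the
#' patient-level offsets and the AR innovations.
#'
#' @param signals named list (one entry per [SPM_SIGNALS]) of lists with
#'   `knots` (data.frame `minute`, `value`), `sd_between`, `sd_within`,
#'   `ar_coef`.
#' @param correlation symmetric positive-definite 5 x 5 matrix in
#'   [SPM_SIGNALS] order.
#' @return Object of class `trajectory_template`.
#' @export
trajectory_template <- function(signals, correlation) {
  missing_sig <- setdiff(SPM_SIGNALS, names(signals))
  if (length(missing_sig))
    stop_contract("template missing signal(s): %s",
                  paste(missing_sig, collapse = ", "))
  for (sig in SPM_SIGNALS) {
    sp <- signals[[sig]]
    stopifnot(is.data.frame(sp$knots), all(c("minute", "value") %in%
                                             names(sp$knots)))
    if (sp$sd_between <= 0 || sp$sd_within <= 0)
      stop_contract("%s: SD parameters must be positive", sig)
    if (sp$ar_coef < 0 || sp$ar_coef >= 1)
      stop_contract("%s: ar_coef must be in [0, 1)", sig)
    if (sig == "SPO2" && any(sp$knots$value > 100))
      stop_contract("SpO2 baseline must not exceed 100%%")
  }
  correlation <- as.matrix(correlation)
  if (!isTRUE(all.equal(correlation, t(correlation))) ||
      inherits(try(chol(correlation), silent = TRUE), "try-error"))
    stop_contract("correlation matrix must be symmetric positive-definite")
  structure(list(signals = signals[SPM_SIGNALS], correlation = correlation),
            class = "trajectory_template")
}

#' Default postoperative trajectory template
#'
#' Encodes the qualitative recovery picture after neonatal cardiac surgery
#' (the arterial switch operation is the motivating case): a near-static
#' heart rate with a mild decline, arterial
#' blood pressures that dip over the first postoperative hours and recover
#' by the end of day 1, and a slow SpO2 decline from ~100% toward ~97%
#' over the week.  The numeric curves are illustrative defaults of the
#' generator — a plausible cohort, not a fit to any clinical dataset — and
#' all quantitative tests compare against these declared values as ground
#' truth.
#'
#' @return A [trajectory_template()].
#' @export
default_template <- function() {
  kn <- function(...) {
    m <- matrix(c(...), ncol = 2L, byrow = TRUE)
    data.frame(minute = m[, 1L], value = m[, 2L])
  }
  signals <- list(
    HR = list(knots = kn(0, 152, 1440, 150, 10080, 140),
              sd_between = 10, sd_within = 4, ar_coef = 0.95),
    ABP_SYS = list(knots = kn(0, 75, 360, 62, 480, 60, 720, 63, 1440, 78,
                              2880, 81, 10080, 85),
                   sd_between = 8, sd_within = 5, ar_coef = 0.95),
    ABP_DIA = list(knots = kn(0, 45, 360, 37, 480, 36, 720, 38, 1440, 46,
                              2880, 48, 10080, 50),
                   sd_between = 5, sd_within = 3, ar_coef = 0.95),
    ABP_MEAN = list(knots = kn(0, 55, 360, 45.5, 480, 44, 720, 46.5, 1440,
                               56.5, 2880, 59, 10080, 61.7),
                    sd_between = 6, sd_within = 4, ar_coef = 0.95),
    SPO2 = list(knots = kn(0, 100, 1440, 99.3, 4320, 98.2, 10080, 97),
                sd_between = 1.2, sd_within = 0.8, ar_coef = 0.95))
  corr <- diag(5)
  rownames(corr) <- colnames(corr) <- SPM_SIGNALS
  set_r <- function(a, b, r) {
    corr[a, b] <<- r; corr[b, a] <<- r
  }
  set_r("HR", "ABP_SYS", -0.15); set_r("HR", "ABP_DIA", -0.10)
  set_r("HR", "ABP_MEAN", -0.15); set_r("HR", "SPO2", 0.05)
  set_r("ABP_SYS", "ABP_DIA", 0.60); set_r("ABP_SYS", "ABP_MEAN", 0.85)
  set_r("ABP_DIA", "ABP_MEAN", 0.85)
  set_r("ABP_SYS", "SPO2", 0.10); set_r("ABP_DIA", "SPO2", 0.10)
  set_r("ABP_MEAN", "SPO2", 0.10)
  trajectory_template(signals, corr)
}

#' Evaluate a template baseline on arbitrary minutes
#'
#' @param template a `trajectory_template`.
#' @param signal one of [SPM_SIGNALS].
#' @param minutes numeric minutes since operation end.
#' @return Numeric baseline values (constant extrapolation beyond knots).
#' @export
template_baseline <- function(template, signal, minutes) {
  kn <- template$signals[[signal]]$knots
  stats::approx(kn$minute, kn$value, xout = minutes, rule = 2L)$y
}

# latent minute-resolution model sampled on a finer grid so the emitted
# raw streams can carry jittered sub-minute timestamps
.fine_res <- 0.25

.generate_latent <- function(template, horizon) {
  M <- as.integer(horizon / .fine_res)
  tf <- (seq_len(M) - 1L) * .fine_res
  Ch <- chol(template$correlation)
  alpha <- drop(rnorm(5L) %*% Ch)                       # patient offsets
  E <- matrix(rnorm(M * 5L), M, 5L) %*% Ch              # correlated innov.
  latent <- matrix(NA_real_, M, 5L,
                   dimnames = list(NULL, SPM_SIGNALS))
  for (j in seq_along(SPM_SIGNALS)) {
    sp <- template$signals[[SPM_SIGNALS[j]]]
    phi_f <- sp$ar_coef^.fine_res                       # per-fine-step AR
    innov_sd <- sp$sd_within * sqrt(1 - phi_f^2)
    x0 <- rnorm(1L, 0, sp$sd_within)                    # stationary start
    ar <- as.numeric(stats::filter(innov_sd * E[, j], phi_f,
                                   method = "recursive", init = x0))
    latent[, j] <- template_baseline(template, SPM_SIGNALS[j], tf) +
      alpha[j] * sp$sd_between + ar
  }
  list(times = tf, values = latent, offsets = alpha)
}

#' Generate a synthetic multi-patient cohort of raw streams
#'
#' Per patient, correlated Gaussian offsets scaled by the between-patient
#' SDs shift the baseline curves, and an AR(1) process with cross-signal
#' correlated innovations adds within-patient noise.  Signals are emitted
#' as irregular raw streams (one sample roughly every `sample_interval`
#' minutes, with jittered sub-minute timestamps) to exercise the
#' resampling stage.  Fully reproducible from `seed`.
#'
#' @param template a [trajectory_template()].
#' @param n_patients number of patients (>= 2).
#' @param horizon monitoring window in minutes (default 7 days).
#' @param seed integer seed (required; the generator keeps no global
#'   state).
#' @param sample_interval mean raw sampling interval in minutes (default
#'   0.5).
#' @return List of patients, each with `patient_id`, `streams` (named list
#'   of [raw_stream()]s), `truth` (list with `grid`: the noise-free-of-
#'   measurement-artifacts latent values at integer minutes, horizon x 5,
#'   and `offsets`).  The template is attached as attribute `template`.
#' @export
generate_cohort <- function(template, n_patients, horizon = 10080L, seed,
                            sample_interval = 0.5) {
  stopifnot(inherits(template, "trajectory_template"))
  if (!is_count(n_patients, 2L)) stop_contract("n_patients must be >= 2")
  if (missing(seed)) stop_contract("an explicit seed is required")
  patients <- with_seed(seed, lapply(seq_len(n_patients), function(i) {
    pid <- sprintf("P%03d", i)
    lat <- .generate_latent(template, horizon)
    streams <- lapply(setNames(SPM_SIGNALS, SPM_SIGNALS), function(sig) {
      t0 <- seq(sample_interval / 2, horizon - sample_interval / 2,
                by = sample_interval)
      t <- sort(pmin(pmax(t0 + runif(length(t0), -0.1, 0.1), 0),
                     horizon - 1e-6))
      idx <- pmin(pmax(round(t / .fine_res) + 1L, 1L),
                  nrow(lat$values))
      raw_stream(pid, sig, t, lat$values[idx, sig])
    })
    grid_idx <- seq(1L, by = as.integer(1 / .fine_res), length.out = horizon)
    list(patient_id = pid, streams = streams,
         truth = list(grid = lat$values[grid_idx, , drop = FALSE],
                      offsets = lat$offsets))
  }))
  attr(patients, "template") <- template
  attr(patients, "seed") <- seed
  patients
}

#' Describe an anomaly to inject into a patient's streams
#'
#' @param kind one of `mean_shift`, `variance_inflation`,
#'   `correlation_break`, `spike_train`.
#' @param signals affected base signals.
#' @param start,end half-open minute interval.
#' @param magnitude shift in local-SD units (`mean_shift`), SD factor
#'   (`variance_inflation`), spike height in within-SD units
#'   (`spike_train`); ignored for `correlation_break`.
#' @return Object of class `anomaly_spec`.
#' @export
anomaly_spec <- function(kind = c("mean_shift", "variance_inflation",
                                  "correlation_break", "spike_train"),
                         signals, start, end, magnitude = 3) {
  kind <- match.arg(kind)
  if (!all(signals %in% SPM_SIGNALS))
    stop_contract("unknown signal(s) in anomaly spec")
  if (!(is.finite(start) && is.finite(end) && start < end))
    stop_contract("anomaly interval must satisfy start < end")
  if (!is.finite(magnitude))
    stop_contract("magnitude must be finite")
  structure(list(kind = kind, signals = signals, start = start, end = end,
                 magnitude = magnitude),
            class = "anomaly_spec")
}

#' Inject anomalies into one patient's raw streams
#'
#' `mean_shift` adds `magnitude` local SDs (the cross-patient SD
#' `sqrt(sd_between^2 + sd_within^2)`) to the affected window;
#' `variance_inflation` scales the deviation from the template baseline by
#' `magnitude`; `correlation_break` regenerates the window from
#' independent (uncorrelated across signals) AR(1) noise around the
#' baseline; `spike_train` adds isolated spikes of `magnitude` within-SD
#' units roughly every 30 minutes.  Minutes outside the spec windows are
#' bit-identical to the input.
#'
#' @param streams named list of [raw_stream()]s for one patient.
#' @param specs list of [anomaly_spec()]s; windows on the same signal must
#'   not overlap.
#' @param seed integer seed for the stochastic anomaly kinds.
#' @param template the [trajectory_template()] the patient was drawn from.
#' @return Modified streams; bookkeeping (spike minutes per signal) in
#'   attribute `injections`.
#' @export
inject <- function(streams, specs, seed, template) {
  if (length(specs) == 0L) return(streams)
  for (sig in SPM_SIGNALS) {
    wins <- do.call(rbind, lapply(specs, function(sp)
      if (sig %in% sp$signals) c(sp$start, sp$end)))
    if (!is.null(wins) && nrow(wins) > 1L) {
      o <- order(wins[, 1L])
      if (any(wins[o, 1L][-1L] < wins[o, 2L][-nrow(wins)]))
        stop_contract("overlapping anomaly windows on %s", sig)
    }
  }
  book <- list()
  streams <- with_seed(seed, {
    for (sp in specs) {
      for (sig in sp$signals) {
        s <- streams[[sig]]
        tpl <- template$signals[[sig]]
        win <- s$times >= sp$start & s$times < sp$end
        if (sp$kind == "mean_shift") {
          sd_loc <- sqrt(tpl$sd_between^2 + tpl$sd_within^2)
          s$values[win] <- s$values[win] + sp$magnitude * sd_loc
        } else if (sp$kind == "variance_inflation") {
          base <- template_baseline(template, sig, s$times[win])
          s$values[win] <- base + (s$values[win] - base) * sp$magnitude
        } else if (sp$kind == "correlation_break") {
          phi <- tpl$ar_coef^.fine_res
          m <- sum(win)
          if (m) {
            ar <- as.numeric(stats::filter(
              rnorm(m, 0, tpl$sd_within * sqrt(1 - phi^2)), phi,
              method = "recursive", init = rnorm(1L, 0, tpl$sd_within)))
            s$values[win] <- template_baseline(template, sig,
                                               s$times[win]) + ar
          }
        } else if (sp$kind == "spike_train") {
          at <- seq(ceiling(sp$start) + 15, sp$end - 1, by = 30)
          pos <- vapply(at, function(a) which.min(abs(s$times - a)), 0L)
          sgn <- sample(c(-1, 1), length(pos), replace = TRUE)
          s$values[pos] <- s$values[pos] +
            sgn * sp$magnitude * tpl$sd_within
          # the grid minute nearest the spiked sample is the one affected
          book[[sig]] <- sort(unique(c(book[[sig]],
                                       round(s$times[pos]))))
        }
        streams[[sig]] <- s
      }
    }
    streams
  })
  attr(streams, "injections") <- book
  streams
}

#' Inject sensor dropouts and spike outliers
#'
#' Removes raw samples inside randomly placed gaps of at least `min_gap`
#' minutes until roughly `dropout_fraction` of each signal's span is
#' silent, and perturbs isolated raw samples at roughly
#' `outlier_fraction` of the minutes by +/- 10 within-patient SDs.
#'
#' @param streams named list of [raw_stream()]s for one patient.
#' @param dropout_fraction,outlier_fraction target fractions in [0, 0.1].
#' @param seed integer seed.
#' @param template the source [trajectory_template()] (sizes the spikes).
#' @param min_gap minimum dropout gap length in minutes (default 3).
#' @return Modified streams; attribute `injections` records, per signal,
#'   the dropped-out minutes and the outlier minutes actually injected.
#' @export
inject_missingness <- function(streams, dropout_fraction, outlier_fraction,
                               seed, template, min_gap = 3L) {
  if (dropout_fraction < 0 || dropout_fraction > 0.1 ||
      outlier_fraction < 0 || outlier_fraction > 0.1)
    stop_contract("fractions must lie in [0, 0.1]")
  if (dropout_fraction == 0 && outlier_fraction == 0) return(streams)
  book <- list()
  streams <- with_seed(seed, {
    for (sig in SPM_SIGNALS) {
      s <- streams[[sig]]
      tpl <- template$signals[[sig]]
      span0 <- floor(min(s$times)); span1 <- floor(max(s$times))
      span_min <- span1 - span0 + 1L
      target <- round(dropout_fraction * span_min)
      taken <- integer(0)
      tries <- 0L
      while (length(taken) < target && tries < 1000L) {
        tries <- tries + 1L
        len <- sample(min_gap:(min_gap + 7L), 1L)
        a <- sample(span0:(span1 - len), 1L)
        cand <- a:(a + len - 1L)
        # keep gaps separated so runs stay distinct and detectable
        if (length(intersect(c(cand - 1L, cand, cand + 1L), taken)))
          next
        taken <- c(taken, cand)
        s$values <- s$values[!(floor(s$times) %in% cand)]
        s$times <- s$times[!(floor(s$times) %in% cand)]
      }
      n_out <- round(outlier_fraction * span_min)
      free <- setdiff(span0:span1, c(taken, taken - 1L, taken + 1L))
      out_min <- integer(0)
      while (length(out_min) < n_out && length(free)) {
        m <- if (length(free) == 1L) free else sample(free, 1L)
        free <- setdiff(free, (m - 3L):(m + 3L))   # keep spikes isolated
        pos <- which.min(abs(s$times - m))
        s$values[pos] <- s$values[pos] +
          sample(c(-1, 1), 1L) * 10 * tpl$sd_within
        out_min <- c(out_min, round(s$times[pos]))
      }
      book[[sig]] <- list(dropout_minutes = sort(taken),
                          outlier_minutes = sort(out_min))
      streams[[sig]] <- s
    }
    streams
  })
  attr(streams, "injections") <- book
  streams
}
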