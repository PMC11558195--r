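#' Construct a raw (irregularly sampled) stream
#'
#' @param patient_id character scalar.
#' @param signal one of [SPM_SIGNALS].
#' @param times numeric, non-decreasing sample times in minutes since
#'   operation end.
#' @param values numeric, finite sample values in signal units.
#' @return Object of class `raw_stream`.
#' @export
raw_stream <- function(patient_id, signal, times, values) {
  if (!signal %in% SPM_SIGNALS)
    stop_data("unknown signal '%s'", signal)
  if (length(times) != length(values))
    stop_contract("times and values must have equal length")
  times <- as.numeric(times); values <- as.numeric(values)
  if (is.unsorted(times))
    stop_data("raw sample times must be non-decreasing (%s, %s)",
              patient_id, signal)
  if (length(values) && any(!is.finite(values)))
    stop_data("raw sample values must be finite (%s, %s)",
              patient_id, signal)
  structure(list(patient_id = as.character(patient_id), signal = signal,
                 times = times, values = values),
            class = "raw_stream")
}

#' Detect dropout intervals in a raw stream
#'
#' A grid minute `m` is silent when no raw sample falls in `[m, m + 1)`.
#' Every maximal run of at least `min_gap` consecutive silent minutes is
#' returned as a half-open interval; the threshold is inclusive, so a
#' 3-minute silence already counts as a dropout at the default.
#'
#' @param stream a [raw_stream()].
#' @param horizon monitoring window length in minutes.
#' @param min_gap minimum silent run length flagged (default 3).
#' @return data.frame with columns `start`, `end` (half-open, minutes),
#'   disjoint and sorted.  An empty stream yields one interval covering the
#'   whole horizon.
#' @export
detect_dropouts <- function(stream, horizon, min_gap = 3L) {
  stopifnot(is_count(horizon, 1L), is_count(min_gap, 1L))
  covered <- rep(FALSE, horizon)
  t <- stream$times[stream$times >= 0 & stream$times < horizon]
  covered[unique(floor(t)) + 1L] <- TRUE
  r <- rle(!covered)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_gap
  data.frame(start = starts[keep] - 1L, end = ends[keep])
}

#' Resample a raw stream to the 1-minute grid
#'
#' Values at integer minutes are obtained by linear interpolation between
#' the neighboring raw samples.  Minutes before the first or after the
#' last raw sample are invalid, as are minutes inside (or whose
#' interpolation would bridge) a dropout gap of at least `min_gap` silent
#' minutes; silences shorter than `min_gap` are interpolated across.
#' Minutes coinciding exactly with a raw sample time reproduce that raw
#' value.
#'
#' @inheritParams detect_dropouts
#' @return A [signal_trace()].
#' @export
resample_to_grid <- function(stream, horizon, min_gap = 3L) {
  if (length(stream$times) < 2L)
    stop_data("insufficient data: need at least 2 raw samples (%s, %s)",
              stream$patient_id, stream$signal)
  t <- stream$times; v <- stream$values
  if (anyDuplicated(t)) {           # average coincident samples
    v <- as.numeric(tapply(v, t, mean))
    t <- sort(unique(t))
  }
  grid <- 0:(horizon - 1L)
  y <- stats::approx(t, v, xout = grid, method = "linear", rule = 1L,
                     ties = mean)$y
  valid <- !is.na(y)
  gaps <- detect_dropouts(stream, horizon, min_gap)
  if (nrow(gaps)) {
    for (g in seq_len(nrow(gaps))) {
      before <- t[t < gaps$start[g]]
      after  <- t[t >= gaps$end[g]]
      t_prev <- if (length(before)) max(before) else -Inf
      t_next <- if (length(after)) min(after) else Inf
      valid[grid > t_prev & grid < t_next] <- FALSE
    }
  }
  y[!valid] <- NA_real_
  signal_trace(stream$patient_id, stream$signal, y, valid)
}

# cache of calibrated threshold multipliers, keyed by (window, alpha)
.hampel_cache <- new.env(parent = emptyenv())

#' Hampel threshold multiplier for a given misidentification rate
#'
#' The Hampel identifier flags a point when its distance from the window
#' median exceeds `t * 1.4826 * MAD`.  The defining parameter is the
#' allowed misidentification rate `alpha`: the probability that an
#' uncontaminated Gaussian point is flagged.  For finite windows the
#' asymptotic multiplier `qnorm(1 - alpha/2)` substantially overshoots
#' that rate (the window median and MAD are noisy), so the default method
#' computes the finite-sample multiplier: the `1 - alpha` quantile of the
#' null ratio `|x - median| / (1.4826 * MAD)` over centered windows of the
#' configured width, estimated once by Monte Carlo with a fixed internal
#' seed and cached per `(window, alpha)`.
#'
#' @param window odd window width in grid minutes.
#' @param alpha allowed misidentification rate in (0, 1).
#' @param method `"finite_sample"` (default) or `"asymptotic"`.
#' @param n_sim Monte-Carlo sample size for the finite-sample calibration.
#' @return Numeric scalar multiplier.
#' @export
hampel_threshold_multiplier <- function(window = 11L, alpha = 0.05,
                                        method = c("finite_sample",
                                                   "asymptotic"),
                                        n_sim = 2e5) {
  method <- match.arg(method)
  if (method == "asymptotic") return(qnorm(1 - alpha / 2))
  key <- sprintf("w%d_a%.10g", window, alpha)
  if (!is.null(.hampel_cache[[key]])) return(.hampel_cache[[key]])
  half <- window %/% 2L
  mult <- with_seed(190643L, {
    x <- rnorm(n_sim + window)
    st <- hampel_window_stats(x, rep(TRUE, length(x)), half, 3L)
    ratio <- abs(x - st$median) / (1.4826 * st$mad)
    # drop edge-truncated windows from the calibration
    core <- (half + 1L):(length(x) - half)
    quantile(ratio[core], 1 - alpha, names = FALSE)
  })
  .hampel_cache[[key]] <- mult
  mult
}

#' Hampel outlier identifier on a gridded series
#'
#' For each valid point the median and the MAD over a centered window
#' (truncated at the series edges, restricted to valid entries) are
#' computed; the point is flagged when `|x - median|` exceeds
#' `t * 1.4826 * MAD` with the multiplier `t` set from the allowed
#' misidentification rate (see [hampel_threshold_multiplier()]).  Flagged
#' points are replaced by their window median.  Windows whose MAD is zero
#' (locally constant readings, plausible at 1-minute resolution) never
#' flag, and points with fewer than 3 valid window entries are left
#' unevaluated.
#'
#' @param x numeric series on the minute grid.
#' @param valid logical validity mask (default: finite entries).
#' @param window odd window width, >= 3 (default 11 minutes).
#' @param alpha allowed misidentification rate (default 0.05).
#' @param threshold `"finite_sample"` or `"asymptotic"` multiplier.
#' @return List with `values` (cleaned series), `flagged` (logical mask of
#'   replacements), `multiplier`, and `n_unevaluated`.
#' @export
hampel_filter <- function(x, valid = NULL, window = 11L, alpha = 0.05,
                          threshold = c("finite_sample", "asymptotic")) {
  threshold <- match.arg(threshold)
  if (!is_count(window, 3L) || window %% 2L == 0L)
    stop_contract("window must be an odd integer >= 3")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_contract("alpha must be in (0, 1)")
  x <- as.numeric(x)
  valid <- if (is.null(valid)) is.finite(x) else as.logical(valid) & is.finite(x)
  mult <- hampel_threshold_multiplier(window, alpha, threshold)
  st <- hampel_window_stats(x, valid, window %/% 2L, 3L)
  evaluated <- valid & !is.na(st$mad)
  flagged <- evaluated & st$mad > 0 &
    abs(x - st$median) > mult * 1.4826 * st$mad
  out <- x
  out[flagged] <- st$median[flagged]
  list(values = out, flagged = flagged, multiplier = mult,
       n_unevaluated = sum(valid & !evaluated))
}

#' Preprocess one patient's raw streams
#'
#' Per signal: dropout detection, gap-aware resampling to the 1-minute
#' grid, then Hampel outlier cleaning on the valid entries.  The report
#' aggregates, over the five signals, the minutes between each signal's
#' first and last raw sample (the evaluated span): how many were lost to
#' dropouts and how many were flagged and replaced as outliers.  Minutes
#' before the first or after the last sample are tallied separately as the
#' pre/post gap fraction of the full horizon.
#'
#' @param streams named list with one [raw_stream()] per canonical signal.
#' @param horizon monitoring window length in minutes.
#' @param config configuration list from [spm_config()].
#' @return List with `record` (a [patient_record()]; a fully silent signal
#'   yields an all-invalid trace and the record is flagged excluded) and
#'   `report` (counts and fractions: `n_total`, `n_dropout`, `n_outlier`,
#'   `dropout_fraction`, `outlier_fraction`, `prepost_fraction`).
#' @export
preprocess_patient <- function(streams, horizon = 10080L,
                               config = spm_config()) {
  missing_sig <- setdiff(SPM_SIGNALS, names(streams))
  if (length(missing_sig))
    stop_data("missing signal(s): %s", paste(missing_sig, collapse = ", "))
  pid <- streams[[1L]]$patient_id
  n_total <- n_dropout <- n_outlier <- n_prepost <- 0L
  traces <- lapply(SPM_SIGNALS, function(sig) {
    s <- streams[[sig]]
    tr <- tryCatch(
      resample_to_grid(s, horizon, config$dropout$min_gap),
      spm_data_error = function(e)
        signal_trace(pid, sig, rep(NA_real_, horizon), rep(FALSE, horizon)))
    hf <- hampel_filter(tr$value, tr$valid, config$hampel$window,
                        config$hampel$alpha, config$hampel$threshold)
    if (length(s$times) && ceiling(min(s$times)) <= floor(max(s$times))) {
      span <- seq.int(max(0L, ceiling(min(s$times))),
                      min(horizon - 1L, floor(max(s$times))))
      n_total   <<- n_total + length(span)
      n_dropout <<- n_dropout + sum(!tr$valid[span + 1L])
      n_outlier <<- n_outlier + sum(hf$flagged[span + 1L])
      n_prepost <<- n_prepost + (horizon - length(span))
    } else {
      n_prepost <<- n_prepost + horizon
    }
    signal_trace(pid, sig, hf$values, tr$valid)
  })
  record <- patient_record(pid, setNames(traces, SPM_SIGNALS),
                           config$exclusion$threshold)
  report <- list(
    patient_id = pid, n_total = n_total, n_dropout = n_dropout,
    n_outlier = n_outlier,
    dropout_fraction = if (n_total) n_dropout / n_total else NA_real_,
    outlier_fraction = if (n_total) n_outlier / n_total else NA_real_,
    prepost_fraction = n_prepost / (length(SPM_SIGNALS) * horizon))
  list(record = record, report = report)
}
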