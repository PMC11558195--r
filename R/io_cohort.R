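#' Construct a gridded signal trace
#'
#' A signal trace holds one signal for one patient on the 1-minute grid
#' `0:(horizon-1)` (minutes since operation end), together with a validity
#' mask.  Invalid minutes (sensor dropout, pre-first/post-last gaps) carry
#' `NA` values.
#'
#' @param patient_id character scalar.
#' @param signal one of [SPM_SIGNALS].
#' @param value numeric vector, one entry per grid minute.
#' @param valid logical vector the same length as `value`; defaults to
#'   `is.finite(value)`.
#' @return An object of class `signal_trace` with fields `patient_id`,
#'   `signal`, `minute`, `value`, `valid`.
#' @export
signal_trace <- function(patient_id, signal, value,
                         valid = is.finite(value)) {
  if (!signal %in% SPM_SIGNALS)
    stop_data("unknown signal '%s' (expected one of %s)", signal,
              paste(SPM_SIGNALS, collapse = ", "))
  if (length(valid) != length(value))
    stop_contract("value and valid must have equal length")
  value <- as.numeric(value)
  valid <- as.logical(valid) & !is.na(valid)
  if (any(!is.finite(value[valid])))
    stop_data("non-finite values at minutes marked valid (%s, %s)",
              patient_id, signal)
  value[!valid] <- NA_real_
  structure(
    list(patient_id = as.character(patient_id), signal = signal,
         minute = seq_along(value) - 1L, value = value, valid = valid),
    class = "signal_trace")
}

#' Assemble a patient record from per-signal traces
#'
#' A patient record bundles the five canonical signal traces on a shared
#' grid.  The per-sensor invalid fraction over the full monitoring horizon
#' is compared against the exclusion threshold (a sensor missing more than
#' that fraction of the monitoring time flags the whole record as
#' excluded); exclusion flags the record but never deletes it.
#'
#' @param patient_id character scalar.
#' @param traces named list with one [signal_trace()] per canonical signal.
#' @param exclusion_threshold maximum tolerated invalid fraction per sensor
#'   (default 0.1).
#' @return Object of class `patient_record` with fields `patient_id`,
#'   `traces`, `horizon`, `invalid_fraction` (per signal), `excluded`.
#' @export
patient_record <- function(patient_id, traces, exclusion_threshold = 0.1) {
  missing_sig <- setdiff(SPM_SIGNALS, names(traces))
  if (length(missing_sig))
    stop_data("patient %s: missing signal(s) %s", patient_id,
              paste(missing_sig, collapse = ", "))
  traces <- traces[SPM_SIGNALS]
  horizon <- length(traces[[1L]]$value)
  for (tr in traces) {
    if (!inherits(tr, "signal_trace"))
      stop_contract("traces must be signal_trace objects")
    if (length(tr$value) != horizon)
      stop_contract("patient %s: traces are on different grids", patient_id)
  }
  invalid_fraction <- vapply(traces, function(tr) mean(!tr$valid), 0)
  structure(
    list(patient_id = as.character(patient_id), traces = traces,
         horizon = horizon, invalid_fraction = invalid_fraction,
         excluded = any(invalid_fraction > exclusion_threshold)),
    class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record %s: %d min, %s>\n", x$patient_id, x$horizon,
              if (x$excluded) "EXCLUDED" else "ok"))
  invisible(x)
}

#' Read a cohort of gridded patient traces from long-format CSV
#'
#' Each file is a long-format table with columns `patient_id`, `signal`,
#' `minute`, `value`, one row per recorded grid minute.  Minutes absent
#' from the table (within `[0, horizon)`) become invalid entries; minutes
#' outside the horizon are dropped.  Unknown signal names and duplicate
#' `(patient, signal, minute)` rows are errors, as is a patient lacking a
#' canonical signal entirely.
#'
#' @param paths character vector of CSV file paths.
#' @param horizon monitoring window length in minutes (default 7 days).
#' @param exclusion_threshold per-sensor invalid fraction above which a
#'   record is flagged excluded (default 0.1).
#' @return List of [patient_record()]s, sorted by patient id.
#' @export
read_cohort <- function(paths, horizon = 10080L, exclusion_threshold = 0.1) {
  stopifnot(length(paths) >= 1L)
  dt <- data.table::rbindlist(lapply(paths, data.table::fread), fill = TRUE)
  need <- c("patient_id", "signal", "minute", "value")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop_format("trace table missing required column(s): %s",
                paste(miss, collapse = ", "))
  bad <- setdiff(unique(dt$signal), SPM_SIGNALS)
  if (length(bad))
    stop_data("unknown signal name(s): %s", paste(bad, collapse = ", "))
  dt <- dt[dt$minute >= 0L & dt$minute < horizon, ]
  key <- paste(dt$patient_id, dt$signal, dt$minute)
  if (anyDuplicated(key))
    stop_data("duplicate (patient, signal, minute) rows, e.g. %s",
              key[anyDuplicated(key)])
  ids <- sort(unique(as.character(dt$patient_id)))
  lapply(setNames(ids, ids), function(pid) {
    sub <- dt[dt$patient_id == pid, ]
    traces <- lapply(SPM_SIGNALS, function(sig) {
      rows <- sub[sub$signal == sig, ]
      if (nrow(rows) == 0L)
        stop_data("patient %s: signal %s absent from input", pid, sig)
      value <- rep(NA_real_, horizon)
      value[rows$minute + 1L] <- rows$value
      signal_trace(pid, sig, value)
    })
    patient_record(pid, setNames(traces, SPM_SIGNALS), exclusion_threshold)
  })
}

#' Write gridded patient records to a long-format CSV
#'
#' Inverse of [read_cohort()]: only valid minutes are written.
#'
#' @param records list of [patient_record()]s.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  rows <- lapply(records, function(rec) {
    data.table::rbindlist(lapply(rec$traces, function(tr) {
      keep <- tr$valid
      data.table::data.table(patient_id = rec$patient_id,
                             signal = tr$signal,
                             minute = tr$minute[keep],
                             value = sprintf("%.17g", tr$value[keep]))
    }))
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' Write raw (irregularly sampled) streams to CSV
#'
#' Long format with columns `patient_id`, `signal`, `time` (float minutes
#' since operation end) and `value`; the dialect emitted by the synthetic
#' cohort generator and accepted by the pipeline's raw input mode.
#'
#' @param patients list of patient entries as returned by
#'   [generate_cohort()] (each with `patient_id` and `streams`).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_raw_streams <- function(patients, path) {
  rows <- lapply(patients, function(p) {
    data.table::rbindlist(lapply(p$streams, function(s) {
      data.table::data.table(patient_id = s$patient_id, signal = s$signal,
                             time = sprintf("%.17g", s$times),
                             value = sprintf("%.17g", s$values))
    }))
  })
  data.table::fwrite(data.table::rbindlist(rows), path)
  invisible(path)
}

#' Read raw streams written by [write_raw_streams()]
#'
#' @param path CSV path with columns `patient_id`, `signal`, `time`, `value`.
#' @return List (one entry per patient id, sorted) of lists with
#'   `patient_id` and `streams` (named list of [raw_stream()]s).
#' @export
read_raw_streams <- function(path) {
  dt <- data.table::fread(path)
  need <- c("patient_id", "signal", "time", "value")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop_format("raw stream table missing column(s): %s",
                paste(miss, collapse = ", "))
  bad <- setdiff(unique(dt$signal), SPM_SIGNALS)
  if (length(bad))
    stop_data("unknown signal name(s): %s", paste(bad, collapse = ", "))
  ids <- sort(unique(as.character(dt$patient_id)))
  lapply(setNames(ids, ids), function(pid) {
    sub <- dt[dt$patient_id == pid, ]
    streams <- lapply(setNames(SPM_SIGNALS, SPM_SIGNALS), function(sig) {
      rows <- sub[sub$signal == sig, ]
      ord <- order(rows$time)
      raw_stream(pid, sig, rows$time[ord], rows$value[ord])
    })
    list(patient_id = pid, streams = streams)
  })
}

#' Write control charts to a tabular file
#'
#' Emits one row per (chart, minute) with columns `minute`, `chart_name`,
#' `statistic`, `limit`, `alarm`.  Floats are written with 17 significant
#' digits so the table round-trips losslessly through
#' [read_chart_table()].
#'
#' @param charts list of `control_chart` objects sharing one minute grid.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_chart_table <- function(charts, path) {
  if (length(charts)) {
    grids <- lapply(charts, `[[`, "minute")
    for (g in grids[-1L])
      if (!identical(g, grids[[1L]]))
        stop_contract("charts must share a common minute grid")
    dt <- data.table::rbindlist(lapply(charts, function(ch) {
      data.table::data.table(
        minute = ch$minute, chart_name = ch$name,
        statistic = ifelse(is.na(ch$statistic), NA_character_,
                           sprintf("%.17g", ch$statistic)),
        limit = ifelse(is.na(ch$limit), NA_character_,
                       sprintf("%.17g", ch$limit)),
        alarm = ch$alarm)
    }))
  } else {
    dt <- data.table::data.table(minute = integer(), chart_name = character(),
                                 statistic = character(), limit = character(),
                                 alarm = logical())
  }
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Read control charts written by [write_chart_table()]
#'
#' @param path CSV path.
#' @return List of `control_chart` objects (the stored table does not carry
#'   the significance level, so `alpha` is `NA`).
#' @export
read_chart_table <- function(path) {
  dt <- data.table::fread(path, colClasses = list(
    numeric = c("statistic", "limit")))
  need <- c("minute", "chart_name", "statistic", "limit", "alarm")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop_format("chart table missing column(s): %s",
                paste(miss, collapse = ", "))
  nms <- unique(dt$chart_name)
  lapply(setNames(nms, nms), function(nm) {
    sub <- dt[dt$chart_name == nm, ]
    control_chart(nm, minute = sub$minute, statistic = sub$statistic,
                  limit = sub$limit, alpha = NA_real_)
  })
}

# time-frame convention for coarse note times: 6-hour blocks anchored to
# calendar days offset from operation end
.frame_start <- c(night = 0L, morning = 360L, afternoon = 720L,
                  evening = 1080L)

#' Read a clinical annotation table
#'
#' Annotations are progress notes (`PN`) or clinical event notes (`CEN`)
#' with either an exact timestamp (`minute`) or a coarse time frame
#' (`day` index, 0-based, plus `frame` in morning/afternoon/evening/night).
#' Coarse frames resolve to fixed 6-hour blocks: night `[00:00, 06:00)`,
#' morning `[06:00, 12:00)`, afternoon `[12:00, 18:00)`, evening
#' `[18:00, 24:00)` of the given day.  Exact timestamps resolve to the
#' zero-width interval `[minute, minute]`.
#'
#' @param path CSV with columns `patient_id`, `kind`, `label` and either
#'   `minute` or both `day` and `frame`.
#' @param horizon monitoring window length in minutes; intervals must fall
#'   inside it.
#' @return data.frame with columns `patient_id`, `kind`, `label`, `start`,
#'   `end` (minutes; `end` exclusive for frames, equal to `start` for exact
#'   timestamps), sorted by patient then time.
#' @export
read_annotations <- function(path, horizon = 10080L) {
  dt <- data.table::fread(path)
  need <- c("patient_id", "kind", "label")
  miss <- setdiff(need, names(dt))
  if (length(miss))
    stop_format("annotation table missing column(s): %s",
                paste(miss, collapse = ", "))
  n <- nrow(dt)
  minute <- if ("minute" %in% names(dt)) dt$minute else rep(NA, n)
  day    <- if ("day" %in% names(dt)) dt$day else rep(NA, n)
  frame  <- if ("frame" %in% names(dt)) dt$frame else rep(NA_character_, n)
  has_min <- !is.na(minute)
  has_frame <- !is.na(day) & !is.na(frame) & frame != ""
  if (any(has_min & has_frame) || any(!has_min & !has_frame))
    stop_format("each annotation needs exactly one of minute or (day, frame)")
  if (!all(dt$kind %in% c("PN", "CEN")))
    stop_data("unknown annotation kind(s): %s",
              paste(setdiff(unique(dt$kind), c("PN", "CEN")), collapse = ", "))
  if (any(has_frame & !frame %in% names(.frame_start)))
    stop_data("unknown time frame(s): %s",
              paste(setdiff(unique(frame[has_frame]), names(.frame_start)),
                    collapse = ", "))
  start <- ifelse(has_min, minute,
                  as.integer(day) * 1440L +
                    unname(.frame_start[as.character(frame)]))
  end <- ifelse(has_min, start, start + 360L)
  if (any(start < 0 | ifelse(has_min, start >= horizon, end > horizon)))
    stop_data("annotation time outside the monitoring horizon")
  out <- data.frame(patient_id = as.character(dt$patient_id),
                    kind = dt$kind, label = dt$label,
                    start = as.integer(start), end = as.integer(end),
                    stringsAsFactors = FALSE)
  out[order(out$patient_id, out$start), , drop = FALSE]
}
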