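#' Assemble the patients x signals x minutes cohort tensor
#'
#' Stacks the gridded traces of a cohort into the three-way array
#' `I x J x K` (patients x signals x minutes) with a matching validity
#' mask, the container on which batch-wise normalization and variable-wise
#' unfolding operate.
#'
#' @param records list of [patient_record()]s sharing one grid.
#' @return Object of class `cohort_tensor`: `data` and `valid` arrays,
#'   `patient_ids`, `signal_labels`, `col_base` (base signal per column),
#'   `col_lag` (lag per column), `n_lags`, `minutes`.
#' @export
build_tensor <- function(records) {
  stopifnot(length(records) >= 1L)
  K <- records[[1L]]$horizon
  horizons <- vapply(records, `[[`, 0L, "horizon")
  if (any(horizons != K))
    stop_contract("records have heterogeneous horizons: %s",
                  paste(unique(horizons), collapse = ", "))
  I <- length(records); J <- length(SPM_SIGNALS)
  ids <- vapply(records, `[[`, "", "patient_id")
  data <- array(NA_real_, dim = c(I, J, K))
  valid <- array(FALSE, dim = c(I, J, K))
  for (i in seq_len(I)) {
    for (j in seq_len(J)) {
      tr <- records[[i]]$traces[[SPM_SIGNALS[j]]]
      data[i, j, ] <- tr$value
      valid[i, j, ] <- tr$valid
    }
  }
  structure(list(data = data, valid = valid, patient_ids = ids,
                 signal_labels = SPM_SIGNALS, col_base = SPM_SIGNALS,
                 col_lag = rep(0L, J), n_lags = 0L, minutes = 0:(K - 1L)),
            class = "cohort_tensor")
}

#' Append time-lagged copies of every signal
#'
#' Grows the signal axis to `J * (n_lags + 1)` columns: the column for
#' signal `j` at lag `l` holds, at minute `k`, the value of `j` at minute
#' `k - l`.  Lags are placed adjacent to their base signal
#' (`HR_lag0, HR_lag1, HR_lag2, ABP_SYS_lag0, ...`).  Minutes `k < l` are
#' invalid for a lag-`l` column (padding would fabricate pre-operative
#' data), as is any minute whose lagged source is invalid.
#'
#' @param tensor a [build_tensor()] result (un-augmented).
#' @param n_lags number of lagged copies per signal (default 2).
#' @return Augmented `cohort_tensor`.
#' @export
lag_augment <- function(tensor, n_lags = 2L) {
  stopifnot(inherits(tensor, "cohort_tensor"))
  if (!is_count(n_lags)) stop_contract("n_lags must be a non-negative integer")
  if (tensor$n_lags != 0L)
    stop_contract("tensor is already lag-augmented")
  if (n_lags == 0L) return(tensor)
  K <- dim(tensor$data)[3L]
  if (n_lags >= K) stop_contract("n_lags (%d) must be < K (%d)", n_lags, K)
  I <- dim(tensor$data)[1L]; J0 <- dim(tensor$data)[2L]
  L <- n_lags + 1L
  data <- array(NA_real_, dim = c(I, J0 * L, K))
  valid <- array(FALSE, dim = c(I, J0 * L, K))
  labels <- character(J0 * L); base <- character(J0 * L); lag <- integer(J0 * L)
  for (j in seq_len(J0)) {
    for (l in 0:n_lags) {
      col <- (j - 1L) * L + l + 1L
      labels[col] <- sprintf("%s_lag%d", tensor$signal_labels[j], l)
      base[col] <- tensor$signal_labels[j]
      lag[col] <- l
      src <- seq_len(K - l)
      dst <- src + l
      data[, col, dst] <- tensor$data[, j, src]
      valid[, col, dst] <- tensor$valid[, j, src]
    }
  }
  structure(list(data = data, valid = valid,
                 patient_ids = tensor$patient_ids, signal_labels = labels,
                 col_base = base, col_lag = lag, n_lags = n_lags,
                 minutes = tensor$minutes),
            class = "cohort_tensor")
}

#' Fit the batch-wise trajectory normalization
#'
#' For every (signal, minute) cell the cross-patient mean and standard
#' deviation over the valid patients are estimated, so that applying the
#' model removes the cohort's shared recovery trajectory and its
#' time-varying variability.  SpO2 columns (all lags) are anchored to the
#' fixed reference of mean 100% and standard deviation 5% instead of the
#' sample statistics.  Cells with fewer than 2 valid patients inherit the
#' statistics of the nearest valid minute of the same column, and
#' standard deviations are floored at `sigma_floor_rel` times the column's
#' median SD so later division stays bounded.
#'
#' @param tensor a (typically lag-augmented) `cohort_tensor`.
#' @param spo2_mu,spo2_sigma fixed SpO2 anchor (defaults 100 and 5).
#' @param sigma_floor_rel relative SD floor (default 1e-3).
#' @return Object of class `normalization_model` with `mu`, `sigma`,
#'   `n_eff` (J x K matrices), `signal_labels`, `col_base`,
#'   `n_fallback_cells`.
#' @export
fit_normalization <- function(tensor, spo2_mu = 100, spo2_sigma = 5,
                              sigma_floor_rel = 1e-3) {
  stopifnot(inherits(tensor, "cohort_tensor"))
  J <- dim(tensor$data)[2L]; K <- dim(tensor$data)[3L]
  mu <- sigma <- matrix(NA_real_, J, K)
  n_eff <- matrix(0L, J, K)
  n_fallback <- 0L
  for (j in seq_len(J)) {
    X <- tensor$data[, j, , drop = TRUE]
    V <- tensor$valid[, j, , drop = TRUE]
    if (is.null(dim(X))) { X <- matrix(X, 1L); V <- matrix(V, 1L) }
    X[!V] <- NA_real_
    n <- colSums(V)
    m <- colMeans(X, na.rm = TRUE)
    ss <- colSums(sweep(X, 2L, m)^2, na.rm = TRUE)
    s <- sqrt(ss / pmax(n - 1L, 1L))
    m[n < 2L] <- NA_real_
    s[n < 2L] <- NA_real_
    n_fallback <- n_fallback + sum(n < 2L)
    mu[j, ] <- fill_nearest(m)
    sigma[j, ] <- fill_nearest(s)
    if (anyNA(mu[j, ]) || anyNA(sigma[j, ]))
      stop_data("column %s has no minute with >= 2 valid patients",
                tensor$signal_labels[j])
    floor_j <- max(sigma_floor_rel * stats::median(sigma[j, ]), 1e-8)
    sigma[j, ] <- pmax(sigma[j, ], floor_j)
    n_eff[j, ] <- n
  }
  is_spo2 <- tensor$col_base == "SPO2"
  mu[is_spo2, ] <- spo2_mu
  sigma[is_spo2, ] <- spo2_sigma
  structure(list(mu = mu, sigma = sigma, n_eff = n_eff,
                 signal_labels = tensor$signal_labels,
                 col_base = tensor$col_base,
                 spo2_mu = spo2_mu, spo2_sigma = spo2_sigma,
                 n_fallback_cells = n_fallback),
            class = "normalization_model")
}

#' Apply (or invert) the batch-wise normalization
#'
#' `apply_normalization()` maps each valid cell to
#' `z = (x - mu[j, k]) / sigma[j, k]`; `denormalize()` is its exact
#' inverse.  Validity masks are preserved.
#'
#' @param tensor a `cohort_tensor` conforming to the model's columns.
#' @param model a [fit_normalization()] result.
#' @return A `cohort_tensor` of the same shape.
#' @export
apply_normalization <- function(tensor, model) {
  .norm_transform(tensor, model, inverse = FALSE)
}

#' @rdname apply_normalization
#' @export
denormalize <- function(tensor, model) {
  .norm_transform(tensor, model, inverse = TRUE)
}

.norm_transform <- function(tensor, model, inverse) {
  stopifnot(inherits(tensor, "cohort_tensor"),
            inherits(model, "normalization_model"))
  J <- dim(tensor$data)[2L]; K <- dim(tensor$data)[3L]
  if (J != nrow(model$mu) || K != ncol(model$mu))
    stop_contract("tensor shape (%d x %d) does not match model (%d x %d)",
                  J, K, nrow(model$mu), ncol(model$mu))
  if (!identical(tensor$signal_labels, model$signal_labels))
    stop_contract("tensor and model signal labels disagree")
  out <- tensor
  I <- dim(tensor$data)[1L]
  for (j in seq_len(J)) {
    mu <- matrix(model$mu[j, ], I, K, byrow = TRUE)
    sg <- matrix(model$sigma[j, ], I, K, byrow = TRUE)
    out$data[, j, ] <- if (inverse) tensor$data[, j, ] * sg + mu
                       else (tensor$data[, j, ] - mu) / sg
  }
  out$data[!out$valid] <- NA_real_
  out
}

#' Unfold the normalized tensor variable-wise
#'
#' Reshapes the `I x J x K` tensor into the `(I K) x J` matrix on which
#' the latent-variable models are trained.  Only (patient, minute) pairs
#' whose J entries are all valid become rows, in patient-major,
#' time-minor order; `row_index` records the provenance of every row so
#' scores can be folded back into per-patient minute series.
#'
#' @param tensor a (normalized) `cohort_tensor`.
#' @return Object of class `unfolded_matrix`: `X`, `row_index` (data.frame
#'   with `patient_id`, `minute`), `signal_labels`, `col_base`, `col_lag`.
#' @export
variable_wise_unfold <- function(tensor) {
  stopifnot(inherits(tensor, "cohort_tensor"))
  I <- dim(tensor$data)[1L]; K <- dim(tensor$data)[3L]
  ok <- apply(tensor$valid, c(1L, 3L), all)   # I x K
  if (is.null(dim(ok))) ok <- matrix(ok, I, K)
  blocks <- vector("list", I)
  idx <- vector("list", I)
  for (i in seq_len(I)) {
    ks <- which(ok[i, ])
    blocks[[i]] <- t(tensor$data[i, , ks, drop = TRUE])
    if (length(ks) == 1L) blocks[[i]] <- matrix(tensor$data[i, , ks], 1L)
    idx[[i]] <- data.frame(patient_id = rep(tensor$patient_ids[i],
                                            length(ks)),
                           minute = tensor$minutes[ks],
                           stringsAsFactors = FALSE)
  }
  X <- do.call(rbind, blocks)
  if (is.null(X)) X <- matrix(0, 0L, dim(tensor$data)[2L])
  colnames(X) <- tensor$signal_labels
  structure(list(X = X, row_index = do.call(rbind, idx),
                 signal_labels = tensor$signal_labels,
                 col_base = tensor$col_base, col_lag = tensor$col_lag,
                 K = K),
            class = "unfolded_matrix")
}

#' Fold a per-row statistic back into per-patient minute series
#'
#' @param values numeric vector, one entry per row of the unfolded matrix.
#' @param row_index the `row_index` of the corresponding
#'   [variable_wise_unfold()] result.
#' @param patient_ids patients (rows of the output), defaulting to those
#'   present in `row_index`.
#' @param K grid length (minutes).
#' @return `length(patient_ids) x K` matrix, `NA` at minutes without a row.
#' @export
fold_statistic <- function(values, row_index,
                           patient_ids = unique(row_index$patient_id), K) {
  stopifnot(length(values) == nrow(row_index))
  out <- matrix(NA_real_, length(patient_ids), K,
                dimnames = list(patient_ids, NULL))
  i <- match(row_index$patient_id, patient_ids)
  keep <- !is.na(i)
  out[cbind(i[keep], row_index$minute[keep] + 1L)] <- values[keep]
  out
}

#' Serialize a normalization model to a tabular file
#'
#' One row per (column, minute) with `signal`, `minute`, `mu`, `sigma`,
#' `n_eff`; full float precision, invertible via
#' [read_normalization()].
#'
#' @param model a `normalization_model`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_normalization <- function(model, path) {
  J <- nrow(model$mu); K <- ncol(model$mu)
  dt <- data.table::data.table(
    signal = rep(model$signal_labels, each = K),
    base = rep(model$col_base, each = K),
    minute = rep(0:(K - 1L), J),
    mu = sprintf("%.17g", t(model$mu)),
    sigma = sprintf("%.17g", t(model$sigma)),
    n_eff = as.integer(t(model$n_eff)))
  data.table::fwrite(dt, path)
  invisible(path)
}

#' @rdname write_normalization
#' @export
read_normalization <- function(path) {
  dt <- data.table::fread(path)
  labels <- unique(dt$signal)
  K <- max(dt$minute) + 1L
  J <- length(labels)
  shape <- function(col) matrix(dt[[col]], J, K, byrow = TRUE)
  base <- dt$base[match(labels, dt$signal)]
  m <- structure(list(mu = shape("mu"), sigma = shape("sigma"),
                      n_eff = shape("n_eff"), signal_labels = labels,
                      col_base = base,
                      spo2_mu = if (any(base == "SPO2"))
                        dt$mu[match(labels[base == "SPO2"][1L], dt$signal)]
                        else 100,
                      spo2_sigma = if (any(base == "SPO2"))
                        dt$sigma[match(labels[base == "SPO2"][1L], dt$signal)]
                        else 5,
                      n_fallback_cells = NA_integer_),
                 class = "normalization_model")
  m
}
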