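#' Construct a control chart
#'
#' A control chart is a per-minute monitoring statistic with its control
#' limit and alarm mask.  Minutes without a statistic (invalid data) are
#' chart gaps: statistic, and hence alarm, are `NA` there — a gap is never
#' an alarm.
#'
#' @param name chart name (conventionally one of `PCA_T2`, `PCA_SPE`,
#'   `SFA_T2D`, `SFA_T2E`).
#' @param minute integer minute grid.
#' @param statistic non-negative statistic per minute (`NA` = gap).
#' @param limit control limit per minute (scalar limits are recycled).
#' @param alpha significance level the limit was computed at.
#' @return Object of class `control_chart` with fields `name`, `minute`,
#'   `statistic`, `limit`, `alarm`, `alpha`.
#' @export
control_chart <- function(name, minute, statistic, limit, alpha) {
  n <- length(minute)
  if (length(statistic) != n)
    stop_contract("statistic and minute must have equal length")
  limit <- rep_len(as.numeric(limit), n)
  statistic <- as.numeric(statistic)
  if (any(statistic < 0, na.rm = TRUE))
    stop_contract("statistics must be non-negative")
  structure(list(name = name, minute = as.integer(minute),
                 statistic = statistic, limit = limit,
                 alarm = statistic > limit, alpha = alpha),
            class = "control_chart")
}

#' @export
print.control_chart <- function(x, ...) {
  ok <- !is.na(x$statistic)
  cat(sprintf("<control_chart %s: %d min (%d valid), %d alarms, alpha=%s>\n",
              x$name, length(x$minute), sum(ok),
              sum(x$alarm, na.rm = TRUE), format(x$alpha)))
  invisible(x)
}

#' Hotelling T2 chart on the retained PCA scores
#'
#' With scores on the variance-consistent scale (training covariance is
#' the identity) the T2 statistic reduces to the squared norm of the
#' retained block, `T2 = ||s[1:c]||^2`, with the flat control limit given
#' by the `1 - alpha` chi-square quantile at `c` degrees of freedom.
#'
#' @param scores matrix of scores, one row per minute (rows of `NA` mark
#'   chart gaps); at least `c` columns.
#' @param c retained-component count (>= 1).
#' @param alpha significance level (default 0.01).
#' @param minutes minute stamps (default `0:(nrow - 1)`).
#' @param name chart name (default `"PCA_T2"`).
#' @return A [control_chart()].
#' @export
t2_chart <- function(scores, c, alpha = 0.01, minutes = NULL,
                     name = "PCA_T2") {
  scores <- as.matrix(scores)
  if (!is_count(c, 1L) || c > ncol(scores))
    stop_contract("c must be an integer in 1..%d", ncol(scores))
  stat <- rowSums(scores[, seq_len(c), drop = FALSE]^2)
  control_chart(name, minutes %||% (seq_len(nrow(scores)) - 1L), stat,
                qchisq(1 - alpha, df = c), alpha)
}

#' SPE chart on the residual PCA scores with windowed limits
#'
#' The squared prediction error is the squared norm of the residual score
#' block, `SPE = ||s[(c+1):J]||^2`.  Its limit at minute `k` uses the Box
#' moment-matching approximation `g_k * chisq_{h_k}(1 - alpha)` with
#' `g_k = v_k / (2 m_k)` and `h_k = 2 m_k^2 / v_k`, where `m_k` and `v_k`
#' are the mean and variance of the training cohort's SPE near minute `k`.
#' To stabilize these small-sample moments the raw training SPE values are
#' pooled over a centered window (default 5 minutes, truncated at the
#' edges) before computing `m_k` and `v_k`.  Minutes where the pooled
#' variance vanishes inherit the limit of the nearest computable minute.
#'
#' @param residual_scores matrix of residual-block scores, one row per
#'   monitored minute.
#' @param training_spe matrix of training SPE values, one row per training
#'   patient and one column per minute (`NA` where that patient has no
#'   valid row).
#' @param window centered pooling window in minutes (default 5).
#' @param alpha significance level (default 0.01).
#' @param minutes minute stamps (default `0:(nrow - 1)`).
#' @return A [control_chart()] named `"PCA_SPE"`.
#' @export
spe_chart <- function(residual_scores, training_spe, window = 5L,
                      alpha = 0.01, minutes = NULL) {
  residual_scores <- as.matrix(residual_scores)
  training_spe <- as.matrix(training_spe)
  K <- nrow(residual_scores)
  if (ncol(training_spe) != K)
    stop_contract("training_spe has %d minutes, monitored series has %d",
                  ncol(training_spe), K)
  stat <- rowSums(residual_scores^2)
  limit <- spe_limit_profile(training_spe, window, alpha)$limit
  control_chart("PCA_SPE", minutes %||% (seq_len(K) - 1L), stat, limit,
                alpha)
}

#' Windowed moment-matching SPE limit profile
#'
#' @inheritParams spe_chart
#' @return List with per-minute `m`, `v`, `g`, `h`, `limit`.
#' @export
spe_limit_profile <- function(training_spe, window = 5L, alpha = 0.01) {
  if (!is_count(window, 1L) || window %% 2L == 0L)
    stop_contract("window must be an odd positive integer")
  half <- window %/% 2L
  ok <- !is.na(training_spe)
  x <- ifelse(ok, training_spe, 0)
  nw <- win_sum(colSums(ok), half)
  s1 <- win_sum(colSums(x), half)
  s2 <- win_sum(colSums(x^2), half)
  m <- ifelse(nw >= 2L, s1 / nw, NA_real_)
  v <- ifelse(nw >= 2L, pmax(s2 - nw * m^2, 0) / (nw - 1L), NA_real_)
  usable <- !is.na(m) & !is.na(v) & m > 0 & v > 0
  g <- h <- limit <- rep(NA_real_, length(m))
  g[usable] <- v[usable] / (2 * m[usable])
  h[usable] <- 2 * m[usable]^2 / v[usable]
  limit[usable] <- g[usable] * qchisq(1 - alpha, df = h[usable])
  if (!any(usable))
    stop_data("no minute has enough training SPE samples for a limit")
  list(m = m, v = v, g = g, h = h, limit = fill_nearest(limit))
}

#' SFA slow- and fast-block T2 charts
#'
#' With slow-feature scores satisfying the identity training covariance,
#' the slow block gives `T2d = ||s[1:d]||^2` with a flat
#' `chisq_d(1 - alpha)` limit and the fast block gives
#' `T2e = ||s[(d+1):J]||^2` with a flat `chisq_(J-d)(1 - alpha)` limit.
#'
#' @param scores matrix of SFA scores (all J columns), one row per minute.
#' @param d slow-feature count (1 <= d < J).
#' @param alpha significance level (default 0.01).
#' @param minutes minute stamps (default `0:(nrow - 1)`).
#' @return List with charts `T2D` and `T2E`.
#' @export
sfa_t2_charts <- function(scores, d, alpha = 0.01, minutes = NULL) {
  scores <- as.matrix(scores)
  J <- ncol(scores)
  if (!is_count(d, 1L) || d >= J)
    stop_contract("d must satisfy 1 <= d < J = %d", J)
  minutes <- minutes %||% (seq_len(nrow(scores)) - 1L)
  t2d <- control_chart("SFA_T2D", minutes,
                       rowSums(scores[, seq_len(d), drop = FALSE]^2),
                       qchisq(1 - alpha, df = d), alpha)
  t2e <- control_chart("SFA_T2E", minutes,
                       rowSums(scores[, (d + 1L):J, drop = FALSE]^2),
                       qchisq(1 - alpha, df = J - d), alpha)
  list(T2D = t2d, T2E = t2e)
}

#' Extract alarm spark intervals from a chart
#'
#' Maximal runs of alarmed minutes as half-open intervals; chart gaps
#' (minutes without a statistic) break runs; runs shorter than
#' `min_duration` are discarded (the default keeps every raw crossing).
#'
#' @param chart a [control_chart()].
#' @param min_duration minimum run length in minutes (default 0).
#' @return data.frame with columns `start`, `end` (half-open minutes).
#' @export
alarm_sparks <- function(chart, min_duration = 0L) {
  stopifnot(inherits(chart, "control_chart"))
  state <- ifelse(is.na(chart$statistic), -1L, as.integer(chart$alarm))
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L & r$lengths >= max(1L, min_duration)
  data.frame(start = chart$minute[starts[keep]],
             end = chart$minute[ends[keep]] + 1L)
}
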