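# internal helpers

spm_stop <- function(class, msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c(class, "spm_error")))
}
stop_format   <- function(msg, ...) spm_stop("spm_format_error", msg, ...)
stop_data     <- function(msg, ...) spm_stop("spm_data_error", msg, ...)
stop_contract <- function(msg, ...) spm_stop("spm_contract_error", msg, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# run code under a given seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# replace NAs by the value at the nearest non-NA index (ties -> left)
fill_nearest <- function(v) {
  ok <- which(!is.na(v))
  if (length(ok) == 0L || length(ok) == length(v)) return(v)
  na <- which(is.na(v))
  fi <- findInterval(na, ok)
  left  <- ifelse(fi >= 1L, ok[pmax(fi, 1L)], NA_integer_)
  right <- ifelse(fi < length(ok), ok[pmin(fi + 1L, length(ok))], NA_integer_)
  dl <- abs(na - left)
  dr <- abs(na - right)
  pick <- ifelse(is.na(left), right,
                 ifelse(is.na(right), left, ifelse(dl <= dr, left, right)))
  v[na] <- v[pick]
  v
}

# truncated centered running sum (half points each side)
win_sum <- function(v, half) {
  n <- length(v)
  cs <- c(0, cumsum(v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cs[hi + 1L] - cs[lo]
}

is_count <- function(x, min = 0L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min &&
    x == as.integer(x)
}
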