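## Internal validation helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE, len = 1L) {
  if (!is.numeric(x) || length(x) != len) {
    stop_config("'%s' must be a numeric vector of length %d", name, len)
  }
  if (!allow_na && anyNA(x)) stop_config("'%s' must not contain NA", name)
  if (any(x < lower, na.rm = TRUE) || any(x > upper, na.rm = TRUE)) {
    stop_config("'%s' must lie in [%s, %s]", name, format(lower), format(upper))
  }
  invisible(x)
}

check_prob <- function(x, name, len = 1L) {
  check_number(x, name, lower = 0, upper = 1, len = len)
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop_config("'%s' must be TRUE or FALSE", name)
  }
  invisible(x)
}

## Derive a stream of per-entity seeds from one base seed, staying inside
## the 32-bit integer range R requires for set.seed().
derive_seeds <- function(seed, n, salt = 0L) {
  base <- (as.double(seed) + 1e6 * salt) %% 2147483629
  as.integer((base + 7919 * seq_len(n)) %% 2147483629) + 1L
}

## P = cumsum(v); returns P[cnt] with the convention P[0] = 0, without
## growing the vector (avoids repeated large copies in hot loops).
prefix_at <- function(P, cnt) {
  out <- numeric(length(cnt))
  pos <- cnt > 0L
  out[pos] <- P[cnt[pos]]
  out
}

## For sorted breakpoints `sorted_vals` return, for each t in `times`,
## #\{sorted_vals < t\} (strict).  Used to index suffix-sum arrays.
count_less_than <- function(times, sorted_vals) {
  findInterval(times, sorted_vals, left.open = TRUE)
}
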