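# Internal helpers shared across modules.

fl_error <- function(msg, class) {
  stop(structure(
    class = c(class, "frailtylog_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

fl_config_error <- function(msg) fl_error(msg, "frailtylog_config_error")
fl_validation_error <- function(msg) fl_error(msg, "frailtylog_validation_error")
fl_input_error <- function(msg) fl_error(msg, "frailtylog_input_error")

# Evaluate `expr` under a local RNG stream, restoring the caller's RNG state.
with_stream_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-participant, per-stream seed below 2^31.
stream_seed <- function(base_seed, participant, stream) {
  (((base_seed %% 1048576L) * 1999L) + participant * 101L + stream) %% 2147483647L
}

# Quantile of a normal truncated to [lo, hi].
qtruncnorm <- function(u, mean, sd, lo = -Inf, hi = Inf) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(plo + u * (phi - plo), mean, sd)
}

# Trailing moving average; element i averages the last min(i, window) values.
trailing_mean <- function(x, window) {
  n <- length(x)
  if (n == 0L) return(numeric(0))
  cs <- cumsum(x)
  idx <- seq_len(n)
  lag <- idx - pmin(idx, window)
  (cs - c(0, cs)[lag + 1L]) / pmin(idx, window)
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)
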