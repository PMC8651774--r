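# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's.
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Deterministic stream of child seeds from one master seed. Values stay
# below 2^31 so they are valid R integer seeds.
seed_stream <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

# Truncated-at-`lower` normal via resampling; errors out after `max_retry`
# rounds so a badly mis-specified profile fails loudly instead of spinning.
rtruncnorm_pos <- function(n, mean, sd, lower = 0, max_retry = 100L) {
  if (n == 0L) return(numeric(0))
  if (sd == 0) {
    if (mean <= lower) abort("degenerate distribution entirely below truncation bound")
    return(rep(mean, n))
  }
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > max_retry) abort("truncated-normal sampling exceeded retry cap")
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stopifnot_scalar_pos <- function(x, what) {
  if (!is_scalar_number(x) || x <= 0) abort(paste0(what, " must be a positive finite number"))
  invisible(x)
}
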