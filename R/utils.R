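# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# classed conditions so callers can distinguish schema / integrity /
# validation / configuration failures programmatically
traj_error <- function(class, message, data = NULL) {
  cond <- structure(
    class = c(class, "trajnet_error", "error", "condition"),
    list(message = message, call = sys.call(-1), data = data)
  )
  stop(cond)
}

traj_warning <- function(message) {
  warning(message, call. = FALSE)
}

# 31-bit polynomial rolling hash of a character scalar, as 8 hex digits;
# used to stamp output files with a config fingerprint without pulling in
# a digest dependency (base bitwOps cannot hold unsigned 32-bit values)
str_hash32 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# derive a per-task seed from a base seed; kept strictly below 2^31
derive_seed <- function(base_seed, index) {
  as.integer((as.double(base_seed) * 7919 + index * 104729) %% 2147483647L)
}

# round half away from zero (the convention used by most statistical
# reporting software); base round() rounds half to even
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= 0 && x == floor(x)
}
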