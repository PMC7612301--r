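# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG seed, restoring the caller's RNG
# state afterwards. seed = NULL evaluates as-is.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# 1-based sample index of time t (seconds from the first sample, which is t = 0).
sample_index <- function(t, sampling_rate) {
  as.integer(round(t * sampling_rate)) + 1L
}

# Indices of the half-open 1 s window [start, start + 1).
segment_indices <- function(start, sampling_rate) {
  i0 <- sample_index(start, sampling_rate)
  seq.int(i0, i0 + as.integer(round(sampling_rate)) - 1L)
}

# Polynomial rolling hash of a character vector, as 8 hex digits. Used only
# to stamp run manifests with a configuration fingerprint.
config_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 4294967291
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
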