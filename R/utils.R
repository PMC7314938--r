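# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# polynomial rolling hash (mod 2^31 - 1) over a deparsed object; stamps
# pipeline artifacts so intermediates from different configurations cannot
# be mixed silently. Exact in doubles: h * 131 + b < 2^53.
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

# seed derived from a user seed and a stage label, kept inside 32-bit range
derive_seed <- function(seed, salt) {
  as.integer((as.numeric(seed) + sum(utf8ToInt(salt)) * 1013) %% 2147483647)
}
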