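`%||%` <- function(a, b) if (is.null(a)) b else a

# Conversion constants: all internal lengths are micrometres.
UM2_PER_MM2 <- 1e6
UM3_PER_MM3 <- 1e9

tg_log <- function(fmt, ...) {
  message(sprintf(paste0("[tilgrad] ", fmt), ...))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0

# Deterministic per-sample substream seed derived from a master seed.
# Kept below 2^31 - 1 so it is a valid R integer seed.
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + index * 104729) %% 2147483647)
}
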