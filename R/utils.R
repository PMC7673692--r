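# internal helpers shared across modules

# Deterministically derive a child seed from a master seed and a stage offset.
# Kept strictly below 2^31 - 1 so it is always a valid R integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# Format a numeric vector so that read-back with as.numeric() is exact
# (17 significant digits round-trips IEEE doubles). NA -> empty cell.
fmt_num <- function(x) {
  out <- ifelse(is.na(x), "", sprintf("%.17g", x))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_validation <- function(...) {
  stop(structure(class = c("vpref_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
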