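# internal helpers shared across modules

# classed condition so callers (and the CLI) can distinguish config, data,
# schema and training failures by exit code
tn_stop <- function(subclass, msg, ...) {
  stop(structure(
    class = c(paste0("tonguenet_", subclass), "tonguenet_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

# round-half-up: R's round() is banker's rounding, the split rule is not
round_half_up <- function(x) floor(x + 0.5)

# derive a child RNG seed; keeps every seed a valid 32-bit integer
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 2048L + as.integer(offset) %% 2048L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x) &&
  x >= 0 && x == floor(x)
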