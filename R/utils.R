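`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# sum of consecutive integer positions a..b (a <= b), exact for doubles in range
pos_sum <- function(a, b) {
  if (b < a) return(0)
  (a + b) * (b - a + 1) / 2
}

# deterministic derived seed for a named substream; keeps results independent
# of call order while remaining a pure function of (seed, label)
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) + h * 1009L) %% 2147483647L
}
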