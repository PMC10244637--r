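# Random batteries for property-style tests. Rates kept strictly inside
# (0.05, 0.95) unless degenerate rates are the point of the test.
random_battery <- function(n, seed) {
  set.seed(seed)
  battery(sprintf("it%02d", seq_len(n)), "rand", runif(n, 0.05, 0.95))
}

random_bits <- function(n, seed) {
  set.seed(seed)
  as.integer(runif(n) < 0.5)
}

# Maximum absolute elementwise difference of two equally long vectors.
max_abs_diff <- function(a, b) max(abs(a - b))
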