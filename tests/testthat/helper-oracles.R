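# Independent closed-form oracles for the Erlang formulas, via the
# direct truncated factorial sums (not the recursion the package uses).

erlang_b_sum <- function(k, a) {
  i <- 0:k
  (a^k / factorial(k)) / sum(a^i / factorial(i))
}

erlang_c_sum <- function(k, a) {
  stopifnot(a < k)
  i <- 0:(k - 1)
  tail_term <- a^k / factorial(k) * k / (k - a)
  tail_term / (sum(a^i / factorial(i)) + tail_term)
}

# shorthand for the calibrated single-district demand
default_demand <- function(...) demand_model(...)
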