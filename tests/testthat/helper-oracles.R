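# Independent brute-force oracles used by property tests. These deliberately
# share no code with the package implementations.

# sort-each-window rolling median (even counts -> mean of middle two via
# stats::median), shrinking windows at the edges, missing-aware
oracle_rolling_median <- function(x, window) {
  n <- length(x)
  h <- window %/% 2
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - h):min(n, i + h)]
    w <- w[!is.na(w)]
    if (!length(w)) NA_real_ else stats::median(w)
  }, numeric(1))
}

# exhaustive scan over all candidate run starts for the sustained rule
oracle_sustained <- function(nf, min_criteria = 2, k_req = 3) {
  ok <- !is.na(nf) & nf >= min_criteria
  n <- length(ok)
  if (n >= k_req) {
    for (s in seq_len(n - k_req + 1)) {
      if (all(ok[s:(s + k_req - 1)])) {
        return(list(positive = TRUE, first = s))
      }
    }
  }
  list(positive = FALSE, first = NA_integer_)
}

grid_times <- function(n, start = "2015-03-01 00:00:00") {
  as.POSIXct(start, tz = "UTC") + (seq_len(n) - 1) * 900
}

# small cohort used by several integration tests
tiny_cohort <- function(n = 60, seed = 202) {
  generate_cohort(cohort_config(n_encounters = n, seed = seed))
}
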