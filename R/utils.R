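# Finite-sample permutation p-value with the add-one convention,
# p = (#{null >= observed} + 1) / (n + 1); two_sided compares absolute
# values. Never returns 0.
add_one_pvalue <- function(null_values, observed, two_sided = FALSE) {
  stopifnot(length(observed) == 1, is.finite(observed))
  if (two_sided) {
    b <- sum(abs(null_values) >= abs(observed))
  } else {
    b <- sum(null_values >= observed)
  }
  (b + 1) / (length(null_values) + 1)
}
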