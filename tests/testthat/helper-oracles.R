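# Independent oracles used to freeze expected values. These deliberately
# avoid the code paths they check.

# Right-tail hypergeometric probability by explicit summation over choose().
hyper_tail_oracle <- function(n_bg, n_set, n_deg, overlap) {
  js <- seq(overlap, min(n_set, n_deg))
  if (length(js) == 0) return(0)
  sum(choose(n_set, js) * choose(n_bg - n_set, n_deg - js)) / choose(n_bg, n_deg)
}

# Brute force: enumerate every DEG draw of size n_deg from the background.
hyper_enum_oracle <- function(n_bg, n_set, n_deg, overlap) {
  draws <- combn(n_bg, n_deg)
  mean(apply(draws, 2, function(d) sum(d <= n_set) >= overlap))
}

# Independent percentile-bootstrap implementation (plain loop).
boot_p_oracle <- function(x, null_value = 100, n_boot = 10000) {
  m <- mean(x)
  if (m == null_value) return(1)
  far <- 0
  for (b in seq_len(n_boot)) {
    mb <- mean(sample(x, length(x), replace = TRUE))
    if ((m > null_value && mb <= null_value) ||
        (m < null_value && mb >= null_value)) far <- far + 1
  }
  min(1, 2 * far / n_boot)
}

# Truth table for the protein evidence matrix, written out case by case.
protein_grade_oracle <- function(means, lo = 150, hi = 200) {
  hi_n <- sum(means > hi)
  mid_n <- sum(means > lo & means <= hi)
  if (hi_n >= 2) return("very_strong")
  if (hi_n == 1) return("strong")
  if (mid_n >= 2) return("strong")
  if (mid_n == 1) return("medium")
  "none"
}

ipa_grade_oracle <- function(p) {
  if (p <= 0.0005) "very_strong"
  else if (p <= 0.005) "strong"
  else if (p <= 0.05) "medium"
  else "none"
}
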