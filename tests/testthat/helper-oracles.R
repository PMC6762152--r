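# Independent oracles used across the test files.  These deliberately use
# the definition-level formulas (literal triple sum, case expansion) and
# share no code with the package's O(N^2) implementations.

# Multi-class MCC as the literal triple sum over (k, l, m), with the
# denominator written as sum_k row_k (S - row_k) per factor.
mcc_triple_sum <- function(cm) {
  N <- nrow(cm)
  S <- sum(cm)
  num <- 0
  for (k in seq_len(N))
    for (l in seq_len(N))
      for (m in seq_len(N))
        num <- num + cm[k, k] * cm[l, m] - cm[m, k] * cm[k, l]
  d1 <- sum(rowSums(cm) * (S - rowSums(cm)))
  d2 <- sum(colSums(cm) * (S - colSums(cm)))
  num / (sqrt(d1) * sqrt(d2))
}

# Binary MCC straight from the 2x2 cells.
mcc_binary_cells <- function(a, b, c, d) {
  (a * d - b * c) / sqrt((a + b) * (b + d) * (a + c) * (c + d))
}

# A batch of seeded random integer confusion matrices.
rand_cms <- function(n, n_classes_range = 2:6, total_range = c(40, 150),
                     seed_base = 1000, symmetric = FALSE) {
  lapply(seq_len(n), function(i) {
    s <- seed_base + i
    N <- n_classes_range[1 + (i %% length(n_classes_range))]
    total <- total_range[1] +
      (i * 37) %% (total_range[2] - total_range[1])
    random_confusion(N, total, seed = s, symmetric = symmetric)
  })
}
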