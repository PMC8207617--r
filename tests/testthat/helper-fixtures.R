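# Shared fixtures, built in code at test time.

# A small long-tail dataset reused across pipeline tests.
small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(
        synthetic_spec(n_samples = 120, n_classes = 8, image_size = 32,
                       tail_exponent = 1.2, seed = 11))
    }
    cache
  }
})

# Independent recurrence oracle for the effective number: one step per
# added sample, Q_1 = 1, Q_n = ((V - 1) / V) * Q_{n-1} + 1 with
# V = 1 / (1 - alpha).
effective_number_recurrence <- function(n, alpha) {
  if (alpha == 1) return(n)        # V -> Inf limit
  q <- 1
  for (k in seq_len(n - 1L)) q <- alpha * q + 1
  q
}

# Brute-force macro F1 straight from the defining formulas, one class at a
# time, independent of the package's vectorized implementation.
brute_macro_f1 <- function(y_true, y_pred) {
  f1s <- vapply(seq_len(ncol(y_true)), function(c) {
    tp <- sum(y_pred[, c] == 1 & y_true[, c] == 1)
    fp <- sum(y_pred[, c] == 1 & y_true[, c] == 0)
    fn <- sum(y_pred[, c] == 0 & y_true[, c] == 1)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    if (p + r > 0) 2 * p * r / (p + r) else 0
  }, numeric(1))
  mean(f1s)
}

random_label_matrix <- function(n, C, p = 0.4) {
  matrix(rbinom(n * C, 1, p), n, C)
}
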