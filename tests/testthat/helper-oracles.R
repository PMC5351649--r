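# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# AUC as explicit pair counting: concordant + half-tied over n1*n0.
pair_count_auc <- function(values, labels, positive = "case") {
  cases <- values[labels == positive]
  controls <- values[labels != positive]
  mean(outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b)))
}

# Youden scan over every candidate threshold of the rule value > t.
brute_youden <- function(values, labels, positive = "case") {
  cases <- values[labels == positive]
  controls <- values[labels != positive]
  thr <- c(-Inf, sort(unique(values)))
  j <- vapply(thr, function(t) {
    mean(cases > t) + mean(controls <= t) - 1
  }, numeric(1))
  max(j)
}

# Logistic log-likelihood at (b0, b1), evaluated directly.
logistic_ll <- function(b0, b1, x, y) {
  eta <- b0 + b1 * x
  sum(y * eta - log1p(exp(eta)))
}

# Per-subject risk score recomputed one cell at a time.
brute_rsf <- function(data, components) {
  vapply(seq_len(nrow(data)), function(i) {
    total <- 0
    for (k in seq_len(nrow(components))) {
      v <- data[[components$mirna[k]]][i]
      s <- if (components$direction[k] == "up") {
        as.integer(v > components$cutoff[k])
      } else {
        as.integer(v < components$cutoff[k])
      }
      total <- total + components$weight[k] * s
    }
    total
  }, numeric(1))
}

# Small wide Ct tibble built in code.
toy_ct_matrix <- function() {
  tibble::tibble(
    sample_id = paste0("s", 1:4),
    target = c(24, 25, 26, 27),
    ref1 = c(20, 20.5, 21, 21.5),
    ref2 = c(22, 22.5, 23, 23.5),
    cel_mir_39 = c(22, 23, 21.5, 22.5),
    negative_control = rep(40, 4)
  )
}
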