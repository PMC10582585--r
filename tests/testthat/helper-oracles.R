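# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive Hamming scan: best (leftmost) window distance to the anchor.
brute_force_hinge <- function(seq, anchor) {
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  a <- strsplit(anchor, "", fixed = TRUE)[[1L]]
  n <- length(s) - length(a) + 1L
  if (n < 1L) return(list(start = NA_integer_, dist = NA_integer_))
  d <- vapply(seq_len(n), function(i) {
    sum(s[i:(i + length(a) - 1L)] != a)
  }, integer(1))
  list(start = which.min(d) - 1L, dist = min(d))
}

# Textbook Pearson r from the definition.
pearson_manual <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# One-way ANOVA F by explicit sum-of-squares decomposition.
anova_f_manual <- function(values, labels) {
  labels <- as.character(labels)
  grand <- mean(values)
  means <- tapply(values, labels, mean)
  ns <- tapply(values, labels, length)
  ssb <- sum(ns * (means - grand)^2)
  ssw <- sum((values - means[labels])^2)
  k <- length(ns)
  (ssb / (k - 1)) / (ssw / (length(values) - k))
}

# Model-implied group-level correlation at the panel generator defaults
# (ratio uniform on 0.5-6 quantized to q2 <= 20; log10 freq =
# 2.2 - 0.35 * ratio + N(0, 0.15); ten ratio bins <=1, 1-5 by 0.5, >5),
# computed by an independent 2000-replicate Monte Carlo from the model
# definition and frozen here.
PANEL_GROUP_R_TARGET <- -0.998

random_protein <- function(n, letters = c("A", "C", "D", "E", "F", "G",
                                          "H", "I", "K", "L", "M", "N",
                                          "P", "Q", "R", "S", "T", "V",
                                          "W", "Y")) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}
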