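# Worked 2-gene, 4-sample cohort used by the hand-checked classifier tests.
# Samples s1, s2 are responders; s3, s4 non-responders.
tiny_cohort <- function() {
  values <- rbind(
    g1 = c(1, 2, 3, 4),
    g2 = c(5, 3, 4, 2)
  )
  colnames(values) <- paste0("s", 1:4)
  expression_cohort("tiny", values, labels = c(1, 1, 0, 0))
}

# Linearly separable fixture: each gene constant within class.
separable_cohort <- function(a = 2, b = -1) {
  values <- rbind(
    g1 = c(a, a, b, b),
    g2 = c(a, a, b, b)
  )
  colnames(values) <- paste0("s", 1:4)
  expression_cohort("separable", values, labels = c(1, 1, 0, 0))
}

# Independent AUC oracle: exhaustive comparison over all (positive, negative)
# pairs, wins = 1, ties = 1/2.
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# Independent nearest-centroid oracle: plain-loop standardization, centroids
# and euclidean score, sharing no code with the package implementation.
oracle_centroid_scores <- function(train_values, train_labels, test_values,
                                   eps = 1e-12) {
  ng <- nrow(train_values)
  m <- numeric(ng); s <- numeric(ng)
  for (g in seq_len(ng)) {
    m[g] <- mean(train_values[g, ])
    s[g] <- sd(train_values[g, ])
  }
  z_train <- (train_values - m) / s
  cpos <- rowMeans(z_train[, train_labels == 1, drop = FALSE])
  cneg <- rowMeans(z_train[, train_labels == 0, drop = FALSE])
  z_test <- (test_values - m) / s
  out <- numeric(ncol(test_values))
  for (j in seq_len(ncol(test_values))) {
    dp <- sqrt(sum((z_test[, j] - cpos)^2))
    dn <- sqrt(sum((z_test[, j] - cneg)^2))
    out[j] <- (dn - dp) / (dn + dp + eps)
  }
  out
}
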