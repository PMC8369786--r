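# Independent oracles kept deliberately naive: they re-derive the quantity a
# different way (enumeration / brute force) and never call the code they check.

# AUC by O(n^2) pair counting: P(pos < neg) + 1/2 P(tie), lower = positive
auc_paircount <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  total <- 0
  for (p in pos) total <- total + sum(p < neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Youden optimum by exhaustive search over observed values under the rule
# "positive iff score < c"; tie-break: max J, then max sensitivity, then
# lowest threshold
youden_exhaustive <- function(scores, labels) {
  labels <- as.logical(labels)
  cand <- sort(unique(scores))
  best <- NULL
  for (c in cand) {
    sens <- mean(scores[labels] < c)
    spec <- mean(scores[!labels] >= c)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && (sens > best$sens + 1e-12 ||
          (abs(sens - best$sens) <= 1e-12 && c < best$cutoff)))) {
      best <- list(cutoff = c, j = j, sens = sens)
    }
  }
  best
}

# Monte-Carlo permutation p-value for a difference in means
perm_test_p <- function(a, b, n_perm = 20000L) {
  obs <- abs(mean(a) - mean(b))
  pooled <- c(a, b)
  na <- length(a)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pooled), na)
    if (abs(mean(pooled[idx]) - mean(pooled[-idx])) >= obs - 1e-12)
      hits <- hits + 1L
  }
  (hits + 1) / (n_perm + 1)
}

# a default scored cohort reused across test files
scored_default_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- score_cohort(generate_cohort(seed = 42))
    cache
  }
})
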