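# Shared fixtures and independent oracles for the test suite.

# small planted dataset: k_rel informative genes at separation delta among
# noise, two balanced classes
planted_dataset <- function(n = 60, p = 100, k_rel = 5, delta = 3,
                            seed = 1) {
  g <- generate_dataset(synthetic_spec(
    n_samples = n, n_genes = p, n_classes = 2,
    class_proportions = c(0.5, 0.5), n_relevant = k_rel,
    effect_size = delta, n_redundant_per_relevant = 0, seed = seed))
  g
}

# dataset holding one exact copy of the class label among Gaussian noise
label_copy_dataset <- function(n = 60, p_noise = 100, seed = 1) {
  set.seed(seed)
  y <- factor(rep(c("a", "b"), each = n / 2))
  X <- cbind(copy = as.numeric(y == "b"),
             matrix(rnorm(n * p_noise), n,
                    dimnames = list(NULL, paste0("noise", seq_len(p_noise)))))
  expression_dataset(X, y)
}

# literal step-down reference for Holm-Bonferroni, written independently of
# the package implementation: rank i is rejected iff every smaller-or-equal
# rank j satisfies p_(j) <= alpha / (m - j + 1)
holm_oracle <- function(p, alpha) {
  m <- length(p)
  if (m == 0) return(logical(0))
  ord <- order(p)
  ok <- p[ord] <= alpha / (m - seq_len(m) + 1)
  pass <- cumprod(ok) == 1
  out <- logical(m)
  out[ord] <- pass
  out
}

# exact upper-tail binomial probability by direct summation (oracle for the
# SCS per-gene p-values)
binom_upper_tail <- function(count, B, prob) {
  k <- count:B
  sum(choose(B, k) * prob^k * (1 - prob)^(B - k))
}

# two-sample t statistic p-value, used as an external association check
t_p <- function(x, y) t.test(x ~ y)$p.value

expect_same_file <- function(a, b) {
  expect_identical(unname(tools::md5sum(a)), unname(tools::md5sum(b)))
}
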