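# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Brute-force Mann-Whitney AUC: enumerate all (positive, negative) pairs,
# ties counting 1/2.
pair_count_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# By-hand LLGMN forward pass: softmax over linear scores on an expanded
# input, component activations summed per class.
softmax_sum_oracle <- function(z_expanded, weights, m_per_class) {
  a <- as.numeric(z_expanded %*% weights)
  e <- exp(a - max(a))
  p <- e / sum(e)
  cls <- rep(1:2, times = rep_len(m_per_class, 2))
  c(sum(p[cls == 1]), sum(p[cls == 2]))
}

# Random two-class posterior rows (points on the 1-simplex).
rand_simplex2 <- function(n) {
  u <- stats::runif(n)
  cbind(u, 1 - u)
}

# Two-Gaussian sample with unit variance at means -mu/+mu; Bayes posterior
# of the positive class is plogis(2 * mu * x).
two_gaussian_sample <- function(n, mu = 1) {
  y <- rep(0:1, length.out = n)
  x <- stats::rnorm(n, mean = ifelse(y == 1, mu, -mu))
  list(x = matrix(x, ncol = 1, dimnames = list(NULL, "z1")), y = y)
}
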