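# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and, where possible, the stats functions the
# package calls) so they can serve as brute-force cross-checks.

# Exact two-sided Mann-Whitney p by full enumeration of rank splits.
mw_enum_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    r <- rank(pooled)
    sum(r[idx]) - n1 * (n1 + 1) / 2
  }
  u_obs <- u_of(seq_len(n1))
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, u_of)
  mu <- n1 * n2 / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration.
fisher_enum_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(xs, function(x)
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1)), numeric(1))
  p_obs <- probs[xs == tab[1, 1]]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Hand step-up Benjamini-Hochberg.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Quadratic least squares by explicit normal equations, with F-test p.
quad_normal_eq <- function(t, y) {
  X <- cbind(1, t, t^2)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  fitted <- as.numeric(X %*% beta)
  rss <- sum((y - fitted)^2)
  mss <- sum((fitted - mean(y))^2)
  df1 <- 2; df2 <- length(y) - 3
  f <- (mss / df1) / (rss / df2)
  list(c = beta[1], b = beta[2], a = beta[3],
       p = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# MCC directly from the closed-form definition.
mcc_oracle <- function(tp, fp, tn, fn) {
  num <- tp * tn - fp * fn
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) 0 else num / den
}

# AUC by exhaustive pairwise comparison of scores.
auc_pairwise <- function(scores_pos, scores_neg) {
  cmp <- outer(scores_pos, scores_neg,
               function(p, n) (p > n) + 0.5 * (p == n))
  mean(cmp)
}

# Brute-force k-NN: full distance sort, majority vote, nearest-neighbour
# fallback on an even split.
knn_brute <- function(train_x, train_y, q, k) {
  d <- apply(train_x, 1, function(r) sqrt(sum((r - q)^2)))
  ord <- order(d, seq_along(d))
  nb <- train_y[ord[seq_len(k)]]
  va <- sum(nb == "aneuploid")
  cls <- if (va * 2 > k) "aneuploid" else if (va * 2 < k) "euploid"
         else train_y[ord[1]]
  list(class = cls, score = va / k)
}
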