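# Independent oracles used to freeze expected values.

# Brute-force two-sided Fisher exact p by full hypergeometric
# enumeration with explicit binomial coefficients (no dhyper).
fisher_oracle <- function(m) {
  a <- m[1, 1]; r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (n == 0) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- vapply(support, function(k)
    choose(r1, k) * choose(n - r1, c1 - k) / choose(n, c1), 0)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-12)]))
}

# Closed-form pooled-variance two-sample Student t p-value.
pooled_t_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y); df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * var(x) + (n2 - 1) * var(y)) / df
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  2 * pt(-abs(t), df)
}
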