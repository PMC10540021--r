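# Independent oracles and small fixtures used across the suite.
# Everything here is computed from first principles (plogis, dnorm,
# explicit sums) so it never shares code with the package internals it
# checks.

# hand-rolled graded-response category probabilities for one item
oracle_cat_probs <- function(theta, a, b) {
  cum <- plogis(a * (theta - b))
  c(1, cum) - c(cum, 0)
}

# brute-force fine-grid posterior moments (default 10,001 points)
oracle_posterior <- function(resp_a, resp_b, resp_k, mu0 = 0, sd0 = 1,
                             lo = -6, hi = 6, n = 10001) {
  th <- seq(lo, hi, length.out = n)
  h <- th[2] - th[1]
  w <- rep(h, n); w[c(1, n)] <- h / 2
  dens <- dnorm(th, mu0, sd0)
  for (j in seq_along(resp_k))
    dens <- dens * vapply(th, function(t)
      oracle_cat_probs(t, resp_a[j], resp_b[[j]])[resp_k[j]], numeric(1))
  z <- sum(w * dens)
  m <- sum(w * th * dens) / z
  v <- sum(w * th^2 * dens) / z - m^2
  list(mean = m, sd = sqrt(v), theta = th, weights = w,
       density = dens / z)
}

# a small deterministic toy bank used in many tests
toy_bank <- function() {
  item_bank(c("t1", "t2", "t3", "t4", "t5"),
            a = c(2.0, 1.5, 2.5, 1.8, 2.2),
            thresholds = list(c(-1, 0, 1),
                              c(-1.5, -0.5, 0.5),
                              c(0, 0.8),
                              c(-0.3, 0.4, 1.2),
                              c(-2, -1, 0.5, 1.5)))
}

# pull the a / thresholds of a bank subset in oracle form
bank_oracle_args <- function(bank, responses) {
  idx <- match(as.character(responses$item_id), bank$item_id)
  list(a = bank$a[idx],
       b = bank$thresholds[idx],
       k = as.integer(responses$category))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
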