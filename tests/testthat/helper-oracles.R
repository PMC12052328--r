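# Independent oracles: deliberately scalar/loop-based re-derivations used to
# cross-check the vectorized implementations. Kept free of package internals.

# category points by explicit enumeration of the three ordered pairs
oracle_category_points <- function(r1, r3, r4,
                                   tie_policy = "pair_incorrect",
                                   one_pair_policy = "zero") {
  if (any(is.na(c(r1, r3, r4)))) {
    return(NA_integer_)
  }
  pairs <- list(c(r1, r3), c(r1, r4), c(r3, r4))
  if (tie_policy == "zero_category" &&
    any(vapply(pairs, function(p) p[1] == p[2], logical(1)))) {
    return(0L)
  }
  n_correct <- sum(vapply(pairs, function(p) p[1] > p[2], logical(1)))
  if (n_correct == 3) {
    2L
  } else if (n_correct == 2) {
    1L
  } else if (n_correct == 1 && one_pair_policy == "one_point") {
    1L
  } else {
    0L
  }
}

# two-sided Mann-Whitney p by brute-force enumeration of group assignments
oracle_mw_enumeration <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  mu <- n1 * length(y) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- combn(length(pooled), n1)
  u_all <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# one-way random-effects components by hand-computed sums of squares
oracle_varcomp <- function(ids, values) {
  ids <- as.character(ids)
  uid <- unique(ids)
  k <- length(uid)
  n_i <- sapply(uid, function(i) sum(ids == i))
  means <- sapply(uid, function(i) mean(values[ids == i]))
  N <- sum(n_i)
  grand <- sum(values) / N
  ssw <- 0
  for (i in uid) ssw <- ssw + sum((values[ids == i] - mean(values[ids == i]))^2)
  msw <- ssw / (N - k)
  ssb <- sum(n_i * (means - grand)^2)
  msb <- ssb / (k - 1)
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  list(
    grand_mean = grand, var_within = msw,
    var_between = max(0, (msb - msw) / n0), n0 = n0
  )
}

# OLS coefficients by solving the normal equations directly
oracle_ols_coefs <- function(X, y) {
  drop(solve(crossprod(X), crossprod(X, y)))
}

# expected category score at chance level: exhaustively average the pairwise
# rules over i.i.d. ratings with the discretized clamped-normal distribution
oracle_chance_total <- function(mu, sigma, scale = c(1, 10),
                                tie_policy = "pair_incorrect",
                                one_pair_policy = "zero") {
  v <- scale[1]:scale[2]
  p <- pnorm(v + 0.5, mu, sigma) - pnorm(v - 0.5, mu, sigma)
  p[1] <- pnorm(scale[1] + 0.5, mu, sigma)
  p[length(v)] <- 1 - pnorm(scale[2] - 0.5, mu, sigma)
  e_cat <- 0
  for (a in v) {
    for (b in v) {
      for (d in v) {
        pts <- oracle_category_points(a, b, d, tie_policy, one_pair_policy)
        e_cat <- e_cat + p[a - scale[1] + 1] * p[b - scale[1] + 1] * p[d - scale[1] + 1] * pts
      }
    }
  }
  4 * e_cat
}
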