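# Fixtures built in code, and deliberately slow brute-force oracles that
# re-derive every estimating quantity from the raw definitions (explicit
# loops over subjects and times, no suffix-sum tricks, no shared code path
# with the package internals).

fixture3 <- function() {
  rt_sample(t = c(1, 2, 3), r = c(2, 3, 3), z = c(0, 1, 0))
}

fixture5 <- function() {
  rt_sample(t = c(0.4, 0.9, 1.3, 1.3, 2.1),
            r = c(1.0, 2.5, 1.7, 2.2, 2.1),
            z = cbind(a = c(0.2, 1.5, -0.3, 0.8, 1.1),
                      b = c(1, 0, 0, 1, 1)))
}

random_sample <- function(n, p = 2, seed) {
  set.seed(seed)
  repeat {
    tt <- round(rexp(3 * n, 1) + 0.05, 2)   # rounding forces occasional ties
    rr <- round(runif(3 * n, 0, 3), 2)
    keep <- which(tt <= rr)
    if (length(keep) >= n) break
  }
  keep <- keep[seq_len(n)]
  z <- matrix(round(rnorm(n * p), 2), n, p)
  rt_sample(tt[keep], rr[keep], z)
}

# risk-set count at time u by direct enumeration
oracle_y <- function(sample, u) {
  sum(sample$t <= u & u <= sample$r)
}

oracle_vhat <- function(sample, beta, times = sort(unique(sample$t))) {
  u_all <- sort(unique(sample$t))
  # the counting process decreases in forward time, so the increments in
  # the exponent carry negative mass
  P <- function(tt) {
    acc <- 0
    for (u in u_all) if (u >= tt) {
      d <- sum(sample$t == u)
      acc <- acc - d / oracle_y(sample, u)
    }
    exp(acc)
  }
  Q_mass <- function(u) {
    tot <- 0
    for (i in seq_len(sample$n))
      if (sample$t[i] == u) tot <- tot + exp(sum(sample$z[i, ] * beta))
    tot / oracle_y(sample, u)
  }
  vapply(times, function(tt) {
    denom <- 0
    for (u in u_all) if (u >= tt) denom <- denom + P(u) * Q_mass(u)
    P(tt) / denom
  }, numeric(1))
}

# double-loop evaluation of the estimating function
oracle_score <- function(sample, beta, weights = NULL) {
  u_all <- sort(unique(sample$t))
  if (is.null(weights)) weights <- rep(1, length(u_all))
  v <- oracle_vhat(sample, beta, u_all)
  p <- ncol(sample$z)
  S <- numeric(p)
  for (j in seq_along(u_all)) {
    u <- u_all[j]
    at_risk <- which(sample$t <= u & u <= sample$r)
    zbar <- colMeans(sample$z[at_risk, , drop = FALSE])
    for (i in seq_len(sample$n)) if (sample$t[i] == u) {
      e <- exp(sum(sample$z[i, ] * beta))
      S <- S + weights[j] * (sample$z[i, ] - zbar) * (e * v[j] + 1)
    }
  }
  S / sample$n
}

# score under the survival-logit parametrization (tilted risk-set mean)
oracle_score_logit <- function(sample, beta) {
  u_all <- sort(unique(sample$t))
  v <- oracle_vhat(sample, beta, u_all)
  p <- ncol(sample$z)
  S <- numeric(p)
  for (j in seq_along(u_all)) {
    u <- u_all[j]
    at_risk <- which(sample$t <= u & u <= sample$r)
    e_risk <- exp(drop(sample$z[at_risk, , drop = FALSE] %*% beta))
    zbar <- colSums(sample$z[at_risk, , drop = FALSE] * e_risk) / sum(e_risk)
    for (i in seq_len(sample$n)) if (sample$t[i] == u) {
      e <- exp(sum(sample$z[i, ] * beta))
      S <- S + (sample$z[i, ] - zbar) * (e * v[j] + 1)
    }
  }
  S / sample$n
}

# product-limit under right truncation, from scratch
oracle_lynden_bell <- function(sample) {
  u_all <- sort(unique(sample$t))
  vapply(u_all, function(tt) {
    f <- 1
    for (u in u_all) if (u > tt) {
      d <- sum(sample$t == u)
      f <- f * (1 - d / oracle_y(sample, u))
    }
    f
  }, numeric(1))
}

num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(k) {
    e <- numeric(length(x)); e[k] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}
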