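test_that("P is the exponential of the negative suffix reverse-hazard sum", {
  s <- rt_sample(c(1, 2), c(2, 2), z = c(0, 1))
  g <- build_event_grid(s)
  expect_equal(compute_P(g), c(exp(-3 / 2), exp(-1 / 2)))  # 1/1 + 1/2, 1/2

  # duplicating every subject leaves the d/y ratios, hence P, unchanged
  s2 <- rt_sample(rep(s$t, 2), rep(s$r, 2), z = rep(c(0, 1), 2))
  expect_equal(compute_P(build_event_grid(s2)), compute_P(g))

  # P is a nondecreasing cdf-type estimate, bounded by 1
  s3 <- random_sample(30, seed = 3)
  P3 <- compute_P(build_event_grid(s3))
  expect_true(all(diff(P3) >= 0))
  expect_true(all(P3 > 0 & P3 < 1))
})

test_that("Q point masses follow the covariate-weighted tie totals", {
  s <- rt_sample(c(1, 2), c(2, 2), z = c(0, 1))
  g <- build_event_grid(s)
  expect_equal(compute_Q_mass(g, log(2), s), c(1, 1))

  # beta = 0 reduces q to d / y
  s2 <- random_sample(25, seed = 7)
  g2 <- build_event_grid(s2)
  expect_equal(compute_Q_mass(g2, c(0, 0), s2), g2$d / g2$y)

  # shifting a scalar covariate by c multiplies every mass by exp(c * beta)
  zc <- s2$z[, 1]
  sa <- rt_sample(s2$t, s2$r, zc)
  sb <- rt_sample(s2$t, s2$r, zc + 0.8)
  expect_equal(compute_Q_mass(build_event_grid(sb), 0.6, sb),
               exp(0.8 * 0.6) * compute_Q_mass(build_event_grid(sa), 0.6, sa))
})

test_that("closed-form baseline odds matches hand arithmetic and the oracle", {
  # two-subject hand computation: P = (e^-1.5, e^-0.5), q = (1, 1/2),
  # D = (e^-1.5 + e^-0.5/2, e^-0.5/2), vhat = (P1/D1, 2) = (1/(1 + e/2), 2)
  s <- rt_sample(c(1, 2), c(2, 2), z = c(0, 0))
  b <- baseline_odds(build_event_grid(s), 0, s)
  expect_equal(b$vhat, c(exp(-1.5) / (exp(-1.5) + exp(-0.5) / 2), 2))
  expect_equal(b$vhat[1], 1 / (1 + exp(1) / 2), tolerance = 1e-12)

  for (seed in 1:4) {
    s <- random_sample(20, seed = seed)
    g <- build_event_grid(s)
    beta <- c(0.4, -0.3)
    b <- baseline_odds(g, beta, s)
    expect_equal(b$vhat, oracle_vhat(s, beta), tolerance = 1e-12)
    expect_true(all(b$vhat > 0))
    # last grid point: P cancels, vhat = 1 / q_m
    expect_equal(b$vhat[length(b$vhat)],
                 1 / b$q_mass[length(b$q_mass)])
    # subject-order permutation invariance
    set.seed(seed)
    perm <- sample(s$n)
    sp <- rt_sample(s$t[perm], s$r[perm], s$z[perm, , drop = FALSE])
    bp <- baseline_odds(build_event_grid(sp), beta, sp)
    expect_equal(bp$vhat, b$vhat)
  }
})

test_that("baseline odds tracks the true t^3 on simulated data, improving with n", {
  rel_err <- function(n, seed) {
    smp <- rt_simulate(sim_config(n = n, seed = seed))
    g <- build_event_grid(smp)
    v <- baseline_odds(g, c(1, 0.5), smp, deriv = FALSE)$vhat
    inner <- g$u >= quantile(smp$t, 0.25) & g$u <= quantile(smp$t, 0.75)
    median(abs(v[inner] - g$u[inner]^3) / g$u[inner]^3)
  }
  e_small <- rel_err(250, seed = 2)
  e_big <- rel_err(3000, seed = 2)
  expect_lt(e_big, 0.10)
  expect_lt(e_big, e_small)

  # and vhat is empirically nondecreasing on model-generated data
  smp <- rt_simulate(sim_config(n = 400, seed = 9))
  v <- baseline_odds(build_event_grid(smp), c(1, 0.5), smp,
                     deriv = FALSE)$vhat
  expect_true(all(diff(v) >= -1e-9))
})

test_that("baseline odds gradient matches finite differences and hand formula", {
  # all-zero covariates: gradient identically zero
  s0 <- rt_sample(c(1, 2, 3), c(2, 3, 3), z = c(0, 0, 0))
  expect_true(all(compute_vhat_grad(build_event_grid(s0), 0, s0) == 0))

  # two-point case, differentiated by hand: with z = (0, 1), beta = 0,
  # q = (1, 1/2), qk = (0, 1/2), D = (e^-1.5 + e^-0.5/2, e^-0.5/2),
  # G = (e^-0.5/2, e^-0.5/2), dv_j = -P_j G_j / D_j^2
  s <- rt_sample(c(1, 2), c(2, 2), z = c(0, 1))
  g <- build_event_grid(s)
  P <- c(exp(-1.5), exp(-0.5))
  D <- c(exp(-1.5) + exp(-0.5) / 2, exp(-0.5) / 2)
  G <- c(exp(-0.5) / 2, exp(-0.5) / 2)
  expect_equal(drop(compute_vhat_grad(g, 0, s)), -P * G / D^2)

  for (seed in 1:4) {
    s <- random_sample(15, seed = seed + 20)
    g <- build_event_grid(s)
    beta <- c(-0.2, 0.5)
    dv <- compute_vhat_grad(g, beta, s)
    for (j in seq_along(g$u)) {
      fd <- num_grad(function(b)
        baseline_odds(g, b, s, deriv = FALSE)$vhat[j], beta)
      expect_equal(dv[j, ], fd, tolerance = 1e-6)
    }
  }
})

test_that("overflow in exp(z' beta) is reported, not propagated", {
  s <- rt_sample(c(1, 2), c(2, 2), z = c(1000, 2000))
  g <- build_event_grid(s)
  expect_error(compute_Q_mass(g, 5, s), "rescal")
})
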