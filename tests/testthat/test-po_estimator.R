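test_that("score matches the brute-force double-loop evaluation", {
  s <- fixture5()
  g <- build_event_grid(s)
  for (beta in list(c(0, 0), c(0.5, -0.2), c(1, 0.5))) {
    expect_equal(po_score(beta, g, s), oracle_score(s, beta),
                 ignore_attr = TRUE, tolerance = 1e-13)
  }
  # weighted version against the same oracle
  w <- lb_weights(suppressWarnings(lynden_bell(g)), "prentice_wilcoxon")
  expect_equal(po_score(c(0.3, 0.1), g, s, weights = w),
               oracle_score(s, c(0.3, 0.1), weights = w),
               ignore_attr = TRUE, tolerance = 1e-13)

  # a constant covariate contributes exactly zero for every beta
  sc <- rt_sample(s$t, s$r, cbind(one = rep(2, 5), a = s$z[, 1]))
  gc <- build_event_grid(sc)
  for (beta in list(c(0, 0), c(1, -1)))
    expect_equal(po_score(beta, gc, sc)[1], 0, ignore_attr = TRUE)

  # random samples, unweighted and optimally weighted
  for (seed in 1:3) {
    sr <- random_sample(20, seed = seed + 80)
    gr <- build_event_grid(sr)
    wo <- lb_weights(suppressWarnings(lynden_bell(gr)), "optimal")
    expect_equal(po_score(c(0.2, 0.4), gr, sr),
                 oracle_score(sr, c(0.2, 0.4)),
                 ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(po_score(c(0.2, 0.4), gr, sr, weights = wo),
                 oracle_score(sr, c(0.2, 0.4), weights = wo),
                 ignore_attr = TRUE, tolerance = 1e-12)
  }
})

test_that("jacobian matches finite differences and is linear in the weights", {
  for (seed in 1:3) {
    s <- random_sample(18, seed = seed + 90)
    g <- build_event_grid(s)
    beta <- c(0.3, -0.4)
    U <- po_jacobian(beta, g, s)
    fd <- vapply(1:2, function(k) {
      num_grad(function(b) po_score(b, g, s)[k], beta, h = 1e-5)
    }, numeric(2))
    expect_equal(U, t(fd), tolerance = 1e-5)
    # constant weights scale the jacobian
    w <- rep(2.5, length(g$u))
    expect_equal(po_jacobian(beta, g, s, weights = w), 2.5 * U,
                 tolerance = 1e-12)
  }
})

test_that("fit recovers the generating coefficients on a large sample", {
  smp <- rt_simulate(sim_config(n = 2000, seed = 42))
  fit <- po_fit(smp)
  expect_true(fit$converged)
  expect_lt(fit$score_norm, 1e-8)
  expect_lt(abs(fit$beta_hat[1] - 1), 3 * fit$se[1])
  expect_lt(abs(fit$beta_hat[2] - 0.5), 3 * fit$se[2])
  # score at the root is numerically zero (re-checked via the public score)
  g <- build_event_grid(smp)
  expect_lt(max(abs(po_score(fit$beta_hat, g, smp))), 1e-8)
  # weighted fits agree to within joint sampling noise
  fit_w <- po_fit(smp, "optimal")
  expect_true(fit_w$converged)
  expect_lt(abs(fit_w$beta_hat[1] - 1), 3 * fit_w$se[1])
})

test_that("fit is equivariant under affine covariate transforms", {
  smp <- rt_simulate(sim_config(n = 150, seed = 7))
  fit <- po_fit(smp)
  # rescale: coefficient scales inversely, z-statistics unchanged
  z2 <- smp$z; z2[, 1] <- z2[, 1] * 4
  fit_sc <- po_fit(rt_sample(smp$t, smp$r, z2))
  expect_equal(fit_sc$beta_hat[1], fit$beta_hat[1] / 4,
               ignore_attr = TRUE, tolerance = 1e-6)
  expect_equal(fit_sc$beta_hat / fit_sc$se, fit$beta_hat / fit$se,
               ignore_attr = TRUE, tolerance = 1e-6)
  # shift: estimate unchanged
  z3 <- smp$z; z3[, 1] <- z3[, 1] + 5
  fit_sh <- po_fit(rt_sample(smp$t, smp$r, z3))
  expect_equal(fit_sh$beta_hat, fit$beta_hat, ignore_attr = TRUE,
               tolerance = 1e-7)
})

test_that("sandwich variance scales like 1/n and rejects degenerate designs", {
  smp <- rt_simulate(sim_config(n = 200, seed = 13))
  g <- build_event_grid(smp)
  fit <- po_fit(smp)
  dup <- rt_sample(rep(smp$t, 2), rep(smp$r, 2),
                   rbind(smp$z, smp$z))
  fit2 <- po_fit(dup)
  expect_equal(fit2$beta_hat, fit$beta_hat, tolerance = 1e-6)
  expect_equal(fit2$cov, fit$cov / 2, tolerance = 1e-5)

  sc <- rt_sample(smp$t, smp$r, cbind(one = rep(1, smp$n)))
  gc <- build_event_grid(sc)
  expect_error(po_sandwich(0, gc, sc), "rank deficient")
})

test_that("bootstrap variance is on the same scale as the sandwich", {
  smp <- rt_simulate(sim_config(n = 150, seed = 21))
  set.seed(99)
  fb <- po_fit(smp, "prentice_wilcoxon", variance = "bootstrap",
               boot_reps = 60)
  fs <- po_fit(smp, "prentice_wilcoxon")
  expect_equal(fb$beta_hat, fs$beta_hat)
  expect_true(all(fb$se / fs$se > 0.6 & fb$se / fs$se < 1.7))
})

test_that("naive fit equals the truncation-aware fit when truncation is idle", {
  set.seed(31)
  n <- 120
  z <- cbind(runif(n, 0, 2), rbinom(n, 1, 0.5))
  tt <- sample_failure_time(z, true_model(), runif(n))
  s <- rt_sample(tt, rep(max(tt), n), z)   # every r_i already equals tau
  f1 <- po_fit(s)
  f2 <- po_fit_naive(s)
  expect_equal(f2$beta_hat, f1$beta_hat)
  expect_equal(f2$cov, f1$cov)
})

test_that("ignoring real truncation biases the fit on paired datasets", {
  # heavy truncation; same datasets fitted both ways
  reps <- 30
  err_adj <- err_naive <- numeric(reps)
  for (i in seq_len(reps)) {
    smp <- rt_simulate(sim_config(n = 300, trunc_upper = 1, seed = 500 + i))
    err_adj[i] <- po_fit(smp, "prentice_wilcoxon")$beta_hat[1] - 1
    err_naive[i] <- po_fit_naive(smp, "prentice_wilcoxon")$beta_hat[1] - 1
  }
  expect_gt(abs(mean(err_naive)), abs(mean(err_adj)))
  expect_gt(abs(mean(err_naive)), 0.1)   # the naive bias is material
})

test_that("survival-logit companion fit matches its oracle and the shared root at 0", {
  s <- fixture5()
  g <- build_event_grid(s)
  # the two risk-set means coincide at beta = 0
  expect_equal(potrunc:::po_score_logit(c(0, 0), g, s),
               po_score(c(0, 0), g, s), ignore_attr = TRUE)
  for (beta in list(c(0.4, -0.1), c(-0.3, 0.6)))
    expect_equal(potrunc:::po_score_logit(beta, g, s),
                 oracle_score_logit(s, beta),
                 ignore_attr = TRUE, tolerance = 1e-12)
  # constant covariate: score identically zero
  sc <- rt_sample(s$t, s$r, cbind(one = rep(1, 5)))
  expect_equal(potrunc:::po_score_logit(0.7, build_event_grid(sc), sc)[1], 0,
               ignore_attr = TRUE)
  # the fit converges on simulated data
  smp <- rt_simulate(sim_config(n = 200, seed = 3))
  fl <- po_fit_logit(smp)
  expect_true(fl$converged)
  expect_true(all(is.finite(fl$se)))
})
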