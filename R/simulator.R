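#' True data-generating model for the simulator
#'
#' Describes a proportional odds model `logit F(t | z) = alpha(t) + z' beta0`
#' by its baseline log-odds function and inverse. The default
#' `alpha(t) = 3 log t` induces the baseline odds `v(t) = t^3` and the
#' conditional distribution `F(t | z) = t^3 e^{z'beta} / (1 + t^3 e^{z'beta})`.
#'
#' @param alpha Strictly increasing baseline log-odds function of time.
#' @param alpha_inv Its inverse.
#' @param beta0 True coefficient vector (default `c(1, 0.5)`).
#' @return Object of class `po_model`.
#' @export
true_model <- function(alpha = function(t) 3 * log(t),
                       alpha_inv = function(x) exp(x / 3),
                       beta0 = c(1, 0.5)) {
  tt <- exp(seq(log(0.05), log(20), length.out = 25))
  if (max(abs(alpha_inv(alpha(tt)) - tt) / tt) > 1e-10)
    stop("alpha_inv is not the inverse of alpha", call. = FALSE)
  if (any(diff(alpha(tt)) <= 0))
    stop("alpha must be strictly increasing", call. = FALSE)
  structure(list(alpha = alpha, alpha_inv = alpha_inv,
                 beta0 = as.numeric(beta0),
                 v = function(t) exp(alpha(t))),
            class = "po_model")
}

#' Simulation configuration
#'
#' Full description of the simulation design: covariates
#' `Z1 ~ Uniform(z1_range)`, `Z2 ~ Bernoulli(z2_prob)`, failure times from
#' the proportional odds model, and an independent uniform right-truncation
#' time `R ~ Uniform(0, trunc_upper)`; a subject is observed only when
#' `T <= R`. With the defaults the truncation rate `P(T > R)` is about 20%
#' for `trunc_upper = 4`, 40% for 2, and 70% for 1.
#'
#' @param n Observed (post-truncation) sample size, at least 50.
#' @param reps Number of Monte-Carlo replications for harness runs.
#' @param beta0 True coefficients (default `c(1, 0.5)`).
#' @param trunc_upper Upper endpoint c of the Uniform(0, c) truncation law.
#' @param seed Root seed; per-replication streams are derived from it.
#' @param estimators Subset of `"unweighted"`, `"prentice_wilcoxon"`,
#'   `"optimal"`, `"naive"` to run in harness studies.
#' @param model A [true_model()].
#' @param z1_range Range of the continuous covariate (default `c(0, 2)`).
#' @param z2_prob Success probability of the binary covariate (default 0.5).
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n = 300L, reps = 1000L, beta0 = c(1, 0.5),
                       trunc_upper = 4, seed = NULL,
                       estimators = c("unweighted", "prentice_wilcoxon",
                                      "optimal"),
                       model = true_model(beta0 = beta0),
                       z1_range = c(0, 2), z2_prob = 0.5) {
  stopifnot(n >= 50L, reps >= 1L, trunc_upper > 0)
  estimators <- match.arg(estimators, c("unweighted", "prentice_wilcoxon",
                                        "optimal", "naive"),
                          several.ok = TRUE)
  structure(list(n = as.integer(n), reps = as.integer(reps),
                 beta0 = as.numeric(beta0), trunc_upper = trunc_upper,
                 seed = seed, estimators = estimators, model = model,
                 z1_range = z1_range, z2_prob = z2_prob),
            class = "sim_config")
}

#' Invert the proportional odds model to draw a failure time
#'
#' Given a uniform draw `u`, returns
#' `T = alpha_inv(logit(u) - z' beta0)`, the conditional quantile transform
#' of the model; for the default baseline,
#' `T = exp((logit(u) - z'beta0) / 3)`.
#'
#' @param z Covariate matrix (one row per draw) or vector for a single draw.
#' @param model A [true_model()].
#' @param u Uniform(0, 1) draws, strictly inside the unit interval.
#' @return Vector of failure times.
#' @export
sample_failure_time <- function(z, model, u) {
  if (is.null(dim(z)))  # one subject's covariates, recycled across draws
    z <- matrix(z, nrow = length(u), ncol = length(model$beta0), byrow = TRUE)
  if (any(u <= 0 | u >= 1))
    stop("uniform draws must lie strictly in (0, 1)", call. = FALSE)
  eta <- drop(z %*% model$beta0)
  model$alpha_inv(stats::qlogis(u) - eta)
}

draw_covariates <- function(config, n) {
  cbind(z1 = stats::runif(n, config$z1_range[1], config$z1_range[2]),
        z2 = stats::rbinom(n, 1L, config$z2_prob))
}

#' Generate a right-truncated sample by rejection
#'
#' Draws `(Z, T, R)` proposals from the configured laws and keeps the first
#' `n` with `T <= R`, mirroring the selection mechanism of right truncation.
#' The realized truncation rate (rejected / proposed) is attached as an
#' attribute so the design's nominal rate is directly checkable.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed overriding `config$seed`; if both are `NULL`
#'   the current RNG state is used.
#' @return An [rt_sample()] with attribute `truncation_rate`.
#' @export
rt_simulate <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- config$n
  acc_t <- numeric(0); acc_r <- numeric(0); acc_z <- NULL
  proposed <- 0L
  while (length(acc_t) < n) {
    batch <- max(2L * n, 1000L)
    z <- draw_covariates(config, batch)
    tt <- sample_failure_time(z, config$model, stats::runif(batch))
    rr <- stats::runif(batch, 0, config$trunc_upper)
    proposed <- proposed + batch
    keep <- tt <= rr
    acc_t <- c(acc_t, tt[keep])
    acc_r <- c(acc_r, rr[keep])
    acc_z <- rbind(acc_z, z[keep, , drop = FALSE])
    if (proposed >= 1e6 && length(acc_t) / proposed < 1e-3)
      stop("acceptance probability below 1e-3; check the configuration",
           call. = FALSE)
  }
  idx <- seq_len(n)
  out <- rt_sample(acc_t[idx], acc_r[idx], acc_z[idx, , drop = FALSE])
  attr(out, "truncation_rate") <- 1 - length(acc_t) / proposed
  out
}

#' Truncation rate of a simulation design
#'
#' `P(T > R)` under the configured laws: the fraction of the latent
#' population excluded by the truncation mechanism. Monte Carlo uses `size`
#' independent proposals; quadrature integrates
#' `E_Z[(1/c) integral_0^c S(r | Z) dr]` with `S(r | z) =
#' 1 / (1 + v(r) e^{z'beta})`, summing exactly over the binary covariate and
#' using adaptive quadrature over the continuous one and over r.
#'
#' @param config A [sim_config()].
#' @param method `"monte_carlo"` or `"quadrature"`.
#' @param size Number of Monte-Carlo proposals.
#' @return Probability in `[0, 1]`.
#' @export
truncation_rate <- function(config, method = c("monte_carlo", "quadrature"),
                            size = 2e5) {
  stopifnot(inherits(config, "sim_config"))
  method <- match.arg(method)
  if (method == "monte_carlo") {
    z <- draw_covariates(config, size)
    tt <- sample_failure_time(z, config$model, stats::runif(size))
    rr <- stats::runif(size, 0, config$trunc_upper)
    return(mean(tt > rr))
  }
  cc <- config$trunc_upper
  b <- config$model$beta0
  v <- config$model$v
  a <- config$z1_range[1]; bz <- config$z1_range[2]
  surv_given_z <- function(z1, z2)  # P(T > r | z) integrated over r in (0, c)
    vapply(z1, function(x) {
      eta <- exp(x * b[1] + z2 * b[2])
      stats::integrate(function(r) 1 / (1 + v(r) * eta), 0, cc,
                       rel.tol = 1e-9)$value / cc
    }, numeric(1))
  mean_over_z1 <- function(z2)
    stats::integrate(function(z1) surv_given_z(z1, z2), a, bz,
                     rel.tol = 1e-8)$value / (bz - a)
  (1 - config$z2_prob) * mean_over_z1(0) + config$z2_prob * mean_over_z1(1)
}
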