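# Closed-form estimation of the baseline odds function v(t) = exp(alpha(t)).
#
# Under the proportional odds model with right truncation the reverse-time
# hazard has a log-linear relationship with the forward hazard, which yields
# a closed-form profile estimate of v at a given coefficient vector beta:
#   P(u_j)  = exp( -sum_{k >= j} d_k / y_k )
#   q_j     = sum_{i: t_i = u_j} exp(z_i' beta) / y_j
#   vhat_j  = P_j / D_j,  D_j = sum_{k >= j} P_k q_k
# The sign in P comes from the reverse-time structure: the counting process
# I(t <= T_i <= R_i) is decreasing in forward time, so its increments carry
# negative mass and the exponent is the negative suffix sum; P estimates the
# marginal cdf of T up to its value at the last event (P ~ F(t)/F(u_m)) and
# is nondecreasing in t. All suffix sums use the closed lower limit (the
# event exactly at t is included). P is carried in log scale and shifted
# before exponentiation so tied, small risk sets cannot underflow.

# internal workhorse: vhat (and optionally its beta-gradient) at one beta
po_baseline_core <- function(grid, sample, beta, deriv = FALSE) {
  beta <- as.numeric(beta)
  p <- grid$p
  if (length(beta) != p)
    stop("beta must have length ", p, call. = FALSE)
  eta <- drop(sample$z %*% beta)
  ezb <- exp(eta)
  if (any(!is.finite(ezb)))
    stop("exp(z' beta) overflowed; consider rescaling covariates", call. = FALSE)
  m <- length(grid$u)
  # per-grid-point exp(z'beta) totals over tied subjects
  sum_ezb <- rowsum_by_group(ezb, grid$group, m)
  q <- sum_ezb / grid$y
  logP <- -rev(cumsum(rev(grid$d / grid$y)))
  shift <- max(logP)
  Ps <- exp(logP - shift)                      # shifted P, max = 1
  A <- rev(cumsum(rev(Ps * q)))                # D_j = exp(shift) * A_j
  if (any(A <= 0)) stop("degenerate denominator in baseline odds", call. = FALSE)
  vhat <- Ps / A
  out <- list(u = grid$u, logP = logP, q = q, vhat = vhat, beta = beta,
              ezb = ezb)
  if (deriv) {
    dv <- matrix(0, m, p)
    for (k in seq_len(p)) {
      qk <- rowsum_by_group(sample$z[, k] * ezb, grid$group, m) / grid$y
      G <- rev(cumsum(rev(Ps * qk)))
      dv[, k] <- -Ps * G / A^2
    }
    out$dvhat <- dv
  }
  out
}

rowsum_by_group <- function(x, group, m) {
  out <- numeric(m)
  agg <- rowsum(x, group)
  out[as.integer(rownames(agg))] <- agg
  out
}

#' Baseline cumulative reverse-hazard exponential P
#'
#' `P(u_j) = exp( -sum_{k >= j} d_k / y_k )`, the exponential of the suffix
#' Nelson-Aalen-type sum of the (negative-mass) reverse-time counting-process
#' increments; a nondecreasing estimate of `F(t) / F(u_m)` up to the
#' exponential-versus-product-limit discretization. It does not depend on the
#' regression coefficients.
#'
#' @param grid An [build_event_grid()] grid.
#' @return Numeric vector over the grid, nondecreasing, in `(0, 1)`, with
#'   `P(u_m) = exp(-d_m / y_m)`.
#' @export
compute_P <- function(grid) {
  stopifnot(inherits(grid, "rt_grid"))
  exp(-rev(cumsum(rev(grid$d / grid$y))))
}

#' Point masses of the covariate-weighted event measure Q
#'
#' `q_j = sum_{i: t_i = u_j} exp(z_i' beta) / y_j`; the measure
#' `Q(t, beta)` is the suffix sum of these masses over grid points `>= t`.
#'
#' @param grid An [build_event_grid()] grid.
#' @param beta Coefficient vector.
#' @param sample The originating [rt_sample()].
#' @return Numeric vector of point masses, all positive.
#' @export
compute_Q_mass <- function(grid, beta, sample) {
  stopifnot(inherits(grid, "rt_grid"))
  po_baseline_core(grid, sample, beta)$q
}

#' Closed-form baseline odds estimate
#'
#' Profiles out the baseline odds function `v(t) = exp(alpha(t))` at a fixed
#' coefficient vector: `vhat(u_j, beta) = P(u_j) / sum_{k >= j} P(u_k) q_k`.
#' Between grid points `vhat` is a right-continuous step function taking the
#' value at the smallest grid point `>= t`; it is only ever evaluated at
#' event times by the estimating equations.
#'
#' @inheritParams compute_Q_mass
#' @param deriv If `TRUE` (default) also return the m x p gradient
#'   `d vhat / d beta`, needed for the estimating-equation Jacobian.
#' @return An object of class `po_baseline`: list with `u`, `p_vals` (P),
#'   `q_mass`, `vhat`, `dvhat` (if requested) and `beta`.
#' @examples
#' s <- rt_sample(c(1, 2), c(2, 2), z = c(0, 0))
#' g <- build_event_grid(s)
#' baseline_odds(g, beta = 0, s)$vhat  # (1 / (1 + e / 2), 2)
#' @export
baseline_odds <- function(grid, beta, sample, deriv = TRUE) {
  stopifnot(inherits(grid, "rt_grid"))
  core <- po_baseline_core(grid, sample, beta, deriv = deriv)
  structure(list(u = core$u, p_vals = exp(core$logP), q_mass = core$q,
                 vhat = core$vhat, dvhat = core$dvhat, beta = core$beta),
            class = "po_baseline")
}

#' Gradient of the baseline odds estimate in beta
#'
#' `d vhat_j / d beta_k = -P_j (sum_{l >= j} P_l qk_l) / D_j^2` with
#' `qk_l = sum_{i: t_i = u_l} z_ik exp(z_i' beta) / y_l`; `P` is free of beta.
#'
#' @inheritParams compute_Q_mass
#' @return m x p numeric matrix.
#' @export
compute_vhat_grad <- function(grid, beta, sample) {
  po_baseline_core(grid, sample, beta, deriv = TRUE)$dvhat
}

#' @export
print.po_baseline <- function(x, ...) {
  cat("Baseline odds estimate on ", length(x$u), " event times at beta = (",
      paste(format(x$beta), collapse = ", "), ")\n", sep = "")
  cat("  vhat range: [", format(min(x$vhat)), ", ", format(max(x$vhat)),
      "]\n", sep = "")
  invisible(x)
}

#' Export baseline diagnostics to CSV
#'
#' Writes `u, P, q, vhat` and one gradient column per covariate, for
#' plotting or inspection of the estimated baseline log-odds
#' `alpha_hat(t) = log vhat(t)`.
#'
#' @param x A [baseline_odds()] object with gradient.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_baseline_csv <- function(x, path) {
  stopifnot(inherits(x, "po_baseline"))
  df <- data.frame(u = x$u, P = x$p_vals, q = x$q_mass, vhat = x$vhat)
  if (!is.null(x$dvhat)) {
    dv <- x$dvhat
    colnames(dv) <- paste0("dvhat_", seq_len(ncol(dv)))
    df <- cbind(df, dv)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
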