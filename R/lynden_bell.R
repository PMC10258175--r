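#' Lynden-Bell product-limit estimator under right truncation
#'
#' Nonparametric estimate of the pooled (baseline) event-time distribution
#' from right-truncated data, built on the same truncation-adjusted risk sets
#' as the regression estimator:
#' `F_hat(u_j) = prod_{k > j} (1 - d_k / y_k)` (empty product = 1 at the last
#' grid point), with survival `S_hat = 1 - F_hat`. Covariates are ignored.
#'
#' If an interior risk set is exhausted (`y_k = d_k` for `k < m`) every
#' earlier `F_hat` is exactly zero; this is permitted but flagged with a
#' warning since it usually signals very heavy truncation or tiny samples.
#'
#' @param grid An [build_event_grid()] grid.
#' @return Object of class `lb_dist`: list with `u`, `F_hat` (nondecreasing,
#'   in `[0, 1]`, reaching 1 at the last event time) and `S_hat = 1 - F_hat`.
#' @examples
#' s <- rt_sample(c(1, 2, 3), c(2, 3, 3), z = c(0, 0, 0))
#' lynden_bell(build_event_grid(s))$F_hat  # 1/4, 1/2, 1
#' @export
lynden_bell <- function(grid) {
  stopifnot(inherits(grid, "rt_grid"))
  m <- length(grid$u)
  frac <- 1 - grid$d / grid$y
  # frac[1] never enters the product (the first risk set is always exactly
  # the tied first events); an exhausted later risk set zeroes F_hat below it
  if (m > 1L && any(frac[-1L] == 0))
    warning("a risk set beyond the first event is exhausted (y = d); ",
            "F_hat is 0 below it")
  # suffix product over k > j; empty product at j = m
  F_hat <- c(rev(cumprod(rev(frac[-1L]))), 1)
  structure(list(u = grid$u, F_hat = F_hat, S_hat = 1 - F_hat),
            class = "lb_dist")
}

#' @export
print.lb_dist <- function(x, ...) {
  cat("Lynden-Bell product-limit estimate on ", length(x$u),
      " event times; F_hat range [", format(min(x$F_hat)), ", 1]\n", sep = "")
  invisible(x)
}

#' Weight functions for the weighted estimating equation
#'
#' Builds a weight per grid point from the Lynden-Bell baseline survival.
#' The martingale structure of right-truncated data runs in reverse time, so
#' a predictable weight may only use information from event times strictly
#' later than the point where it is applied. `S_hat(u_j)` satisfies this
#' exactly: its product runs over grid points `k > j`. (The forward-time
#' left limit would fold the event's own factor `1 - d_j / y_j` into its
#' weight and correlate it with the event increment.)
#' * `prentice_wilcoxon`: `W_j = S_hat(u_j)`, the rank-test-like
#'   downweighting of late events;
#' * `optimal`: `W_j = S_hat(u_j) (1 - S_hat(u_j))`, the plug-in of the
#'   minimum-variance weight `w(t) = S(t)(1 - S(t))`, bounded by 1/4.
#'
#' Both schemes vanish at the last event time (where `S_hat = 0`), which
#' simply removes that event's score contribution — the region where the
#' profiled baseline odds is least stable.
#'
#' @param dist A fitted [lynden_bell()] distribution.
#' @param scheme `"prentice_wilcoxon"` or `"optimal"`.
#' @return Numeric weight vector over the grid points.
#' @export
lb_weights <- function(dist, scheme = c("prentice_wilcoxon", "optimal")) {
  stopifnot(inherits(dist, "lb_dist"))
  scheme <- match.arg(scheme)
  switch(scheme,
         prentice_wilcoxon = dist$S_hat,
         optimal = dist$S_hat * (1 - dist$S_hat))
}

#' Export the Lynden-Bell estimate to CSV
#'
#' @param dist A [lynden_bell()] object.
#' @param path Output CSV path; columns `u, F_hat, S_hat`.
#' @return `path`, invisibly.
#' @export
write_lynden_bell_csv <- function(dist, path) {
  stopifnot(inherits(dist, "lb_dist"))
  utils::write.csv(data.frame(u = dist$u, F_hat = dist$F_hat,
                              S_hat = dist$S_hat),
                   path, row.names = FALSE)
  invisible(path)
}
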