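# potrunc

Proportional odds regression for **right-truncated** time-to-event data.

## The problem

In retrospective designs a case is recorded only if its event happened
before a subject-specific cutoff: classically, incubation periods of
transfusion-associated AIDS are observed only for patients diagnosed before
the end of study, so each event time `T` is observed only when it does not
exceed its right-truncation time `R`. Short times are oversampled, and any
analysis that ignores the selection is biased.

`potrunc` is for biostatisticians and epidemiologists who want
covariate effects on such data with an odds-ratio interpretation. It fits
the semiparametric proportional odds model

    logit F(t | z) = alpha(t) + z' beta,

where `alpha` is an unspecified nondecreasing baseline log-odds function.
The package exploits the reverse-time (retro) hazard
`lambda^B = f / F`, which under this model has a simple relationship with
the baseline odds `v(t) = exp(alpha(t))`: `v` is profiled out **in closed
form** on the grid of distinct event times,

    P_j  = exp( - sum_{k >= j} d_k / y_k )         (cdf-type suffix estimate)
    q_j  = sum_{i: t_i = u_j} exp(z_i' beta) / y_j
    vhat_j = P_j / sum_{k >= j} P_k q_k,

with `y_j` the truncation-adjusted at-risk count, and plugged into a
Newton-solvable estimating equation

    (1/n) sum_j W(u_j) sum_{i: t_i = u_j}
          (z_i - zbar_j) ( exp(z_i' beta) vhat_j + 1 )  =  0.

Weights `W` built from the Lynden-Bell product-limit estimator
(Prentice-Wilcoxon `S_LB`, or the minimum-variance `S_LB (1 - S_LB)`)
substantially improve efficiency and stability; variances come from a
sandwich estimator (or a subject bootstrap), and a truncation-ignoring fit
is included for sensitivity analysis. A simulator and Monte-Carlo harness
reproduce bias / SSE / SEE / coverage tables for the whole machinery.

## Worked example

```r
library(potrunc)

## simulate a right-truncated cohort: baseline odds t^3, beta = (1, 0.5),
## truncation R ~ Uniform(0, 4)  (~20% of the latent population excluded)
smp <- rt_simulate(sim_config(n = 300, trunc_upper = 4, seed = 11))
attr(smp, "truncation_rate")
#> [1] 0.185

po_fit(smp, weight_scheme = "optimal")
#> Proportional odds fit under right truncation (optimal weights, n = 300)
#>      coef     se     z lower95 upper95
#> z1 1.1316 0.2415 4.685  0.6582   1.605
#> z2 0.5864 0.2477 2.367  0.1009   1.072
#> Converged in 4 iteration(s); max |score| = 1.09e-13; variance: sandwich
```

The coefficients are log odds ratios: `exp(1.13) ≈ 3.1` multiplies the odds
of failure by time `t` per unit of `z1`, and both 95% Wald intervals cover
the generating values (1 and 0.5). Real data come in through
`read_rt_sample("data.csv", covariates = c("age"))` (columns `time`,
`trunc`, covariates), and `lynden_bell(build_event_grid(smp))` gives the
nonparametric baseline distribution. A thin command-line front end for
simulation, fitting and the Monte-Carlo tables lives in
`inst/cli/trunc-po.R`.

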