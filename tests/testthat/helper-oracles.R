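# Independent oracles shared across tests.

# direct quadrature of the pulse signal; independent of the closed forms
quad_repair <- function(params, dose, a, b) {
  -stats::integrate(function(t) p_ar_pulse(params, dose, t), a, b,
                    abs.tol = 1e-12, rel.tol = 1e-12,
                    subdivisions = 1000L)$value
}

# random positive parameter sets on scales spanning the fitted values
random_params <- function() {
  ar_params(10^stats::runif(1, -1, 2),
            10^stats::runif(1, -1, 2),
            10^stats::runif(1, -1.5, 0.5))
}

# lesion-count bookkeeping for a two-priming-dose mutation experiment,
# built directly from the survival recursion (counts in units of mu1);
# the challenge's own repair factor exp(-xi_D3) is common to both arms and
# cancelled analytically so the ratio never underflows
two_priming_bookkeeping <- function(params, d1, d2, d3, dt1, dt2) {
  f <- function(D, t) f_antiderivative(params, D, t)
  n12 <- (d2 + d1 * exp(f(d1, dt1) - f(d1, 0))) *
    exp(f(d1, dt1 + dt2) - f(d1, dt1) + f(d2, dt2) - f(d2, 0))
  1 - (d3 + n12) * exp(-f(d1, dt1 + dt2) - f(d2, dt2)) / d3
}

# the worked-example parameter set used throughout the published figures
example_params <- function() ar_params(1, 1, 0.7)
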