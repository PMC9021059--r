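# Vectorised mu-free delta kernels used both by the user-facing wrappers and
# by the fitting objective (which must stay warning-free and fast).
.delta_lesions_kernel <- function(alpha0, alpha1, alpha2, d1, d2, dt, T) {
  fT  <- .f_anti(alpha0, alpha1, alpha2, d1, T)
  fdt <- .f_anti(alpha0, alpha1, alpha2, d1, dt)
  f0  <- .f_anti(alpha0, alpha1, alpha2, d1, 0)
  1 - exp(fT - fdt) - (d1 / d2) * exp(fT - f0)
}

.delta_mutations_kernel <- function(alpha0, alpha1, alpha2, d1, d2, dt) {
  fdt <- .f_anti(alpha0, alpha1, alpha2, d1, dt)
  f0  <- .f_anti(alpha0, alpha1, alpha2, d1, 0)
  1 - exp(-fdt) - (d1 / d2) * exp(-f0)
}

new_delta_result <- function(delta, scheme, inputs) {
  structure(list(delta = delta,
                 yonezawa_effect = delta > 0,
                 scheme = scheme,
                 inputs = inputs),
            class = "delta_result")
}

#' @export
print.delta_result <- function(x, ...) {
  cat(sprintf("delta (%s scheme): %s\n", x$scheme,
              paste(signif(x$delta, 6), collapse = ", ")))
  cat(sprintf("Yonezawa effect present (delta > 0): %s\n",
              paste(x$yonezawa_effect, collapse = ", ")))
  invisible(x)
}

.warn_high_challenge <- function(params, d2) {
  # heuristic validity guard: the model is built for challenging doses that
  # are not too large relative to the dose-decay scale
  if (any(params$alpha1 * d2 > 10))
    warning("challenging dose is large on the model's dose scale ",
            "(alpha1 * D2 > 10); delta predictions may be unreliable",
            call. = FALSE)
}

#' Observed delta from event counts
#'
#' The empirical Yonezawa-effect statistic
#' \eqn{\delta = 1 - (N_{1+2}/n_{1+2}) / (N_2/n_2)}: one minus the ratio of
#' the event frequency under priming + challenging dose to the frequency
#' under the challenging dose alone. Negative values mean no protective
#' effect (they are retained, not clamped, since they still calibrate the
#' model).
#'
#' @param n2_events,n2_denom Events and denominator for the challenge-only
#'   arm; `n2_events` must be positive.
#' @param n12_events,n12_denom Events and denominator for the primed arm.
#' @return Numeric delta (vectorised).
#' @export
delta_from_counts <- function(n2_events, n2_denom, n12_events, n12_denom) {
  if (any(n2_events <= 0))
    stop("delta is undefined when 'n2_events' is zero", call. = FALSE)
  if (any(n2_denom <= 0) || any(n12_denom <= 0))
    stop("denominators must be positive", call. = FALSE)
  1 - (n12_events / n12_denom) / (n2_events / n2_denom)
}

#' Model delta for DNA lesions at finite observation time
#'
#' Fractional reduction of unrepaired lesions at observation time `T` when
#' the challenge `d2` is primed by `d1` given `dt` hours earlier. With `mu`
#' omitted the mu-free form is used,
#' \deqn{\delta = 1 - e^{f(D_1,T) - f(D_1,\Delta t)}
#'   - (D_1/D_2)\, e^{f(D_1,T) - f(D_1,0)},}
#' which all fitting routines rely on; with `mu` supplied the full form
#' including the background term \eqn{\mu_0} is evaluated (identical when
#' `mu0 = 0`).
#'
#' @inheritParams p_ar_pulse
#' @param d1,d2 Priming and challenging doses (Gy), `d2 > 0`.
#' @param dt Inter-dose interval (h), `0 < dt < T`.
#' @param T Observation time (h) since the priming dose.
#' @param mu Optional [lesion_params()].
#' @return A `delta_result` object.
#' @export
delta_lesions <- function(params, d1, d2, dt, T, mu = NULL) {
  params <- as_ar_params(params)
  if (any(d2 <= 0)) stop("delta is undefined for 'd2' = 0", call. = FALSE)
  if (any(d1 < 0)) stop("'d1' must be nonnegative", call. = FALSE)
  if (any(dt < 0)) stop("'dt' must be nonnegative", call. = FALSE)
  if (any(dt >= T)) stop("'dt' must be smaller than 'T'", call. = FALSE)
  .warn_high_challenge(params, d2)
  if (is.null(mu)) {
    delta <- .delta_lesions_kernel(params$alpha0, params$alpha1, params$alpha2,
                                   d1, d2, dt, T)
  } else {
    if (!inherits(mu, "lesion_params"))
      stop("'mu' must be a lesion_params object", call. = FALSE)
    n01 <- mu$mu0 + mu$mu1 * d1
    n02 <- mu$mu1 * d2
    f <- function(D, t) f_antiderivative(params, D, t)
    delta <- (n02 * (1 - exp(f(d1, T) - f(d1, dt))) -
                n01 * exp(f(d1, T) - f(d1, 0))) / n02
  }
  new_delta_result(delta, "lesions",
                   list(params = params, d1 = d1, d2 = d2, dt = dt, T = T,
                        mu = mu))
}

#' Model delta for stable mutations
#'
#' The late-effect (repair-completed, \eqn{T \to \infty}) form
#' \deqn{\delta = 1 - e^{-f(D_1,\Delta t)} - (D_1/D_2)\, e^{-\xi_{D_1}}.}
#' As `dt` grows the value falls to the asymptote [delta_min()].
#'
#' @inheritParams delta_lesions
#' @return A `delta_result` object.
#' @export
delta_mutations <- function(params, d1, d2, dt) {
  params <- as_ar_params(params)
  if (any(d2 <= 0)) stop("delta is undefined for 'd2' = 0", call. = FALSE)
  if (any(d1 < 0)) stop("'d1' must be nonnegative", call. = FALSE)
  if (any(dt < 0)) stop("'dt' must be nonnegative", call. = FALSE)
  .warn_high_challenge(params, d2)
  delta <- .delta_mutations_kernel(params$alpha0, params$alpha1, params$alpha2,
                                   d1, d2, dt)
  new_delta_result(delta, "mutations",
                   list(params = params, d1 = d1, d2 = d2, dt = dt))
}

#' Asymptotic lower bound of delta
#'
#' \eqn{\delta_{\min} = \lim_{\Delta t \to \infty} \delta =
#' -(D_1/D_2) e^{-\xi_{D_1}}}: when the gap is so long that the priming
#' signal has fully decayed, the primed arm simply carries the extra `d1`
#' lesions and delta turns (slightly) negative.
#'
#' @inheritParams delta_lesions
#' @return Numeric (vectorised), <= 0.
#' @export
delta_min <- function(params, d1, d2) {
  params <- as_ar_params(params)
  if (any(d2 <= 0)) stop("delta is undefined for 'd2' = 0", call. = FALSE)
  if (any(d1 < 0)) stop("'d1' must be nonnegative", call. = FALSE)
  -(d1 / d2) * exp(-xi_dose(params, d1))
}

#' Is the priming gap short enough for a protective effect?
#'
#' Tests the condition under which \eqn{\delta \ge 0}:
#' \eqn{f(D_1, \Delta t) \ge -\ln(e^{-f(D_1,T)} - (D_1/D_2) e^{-\xi_{D_1}})}
#' for the lesion endpoint, and with the first term replaced by 1 for the
#' mutation endpoint (`T = Inf`). Because `f(D1, .)` decreases
#' monotonically from \eqn{\xi_{D_1}} to 0, the boundary interval is found
#' by a bracketed root search.
#'
#' @inheritParams delta_lesions
#' @param T Observation time (h); `Inf` selects the mutation endpoint.
#' @return A list with elements `ok` (logical: delta >= 0 at `dt`),
#'   `boundary_dt` (largest protective gap, `NA` if the condition holds for
#'   no positive gap), and `satisfiable` (`FALSE` when the right-hand side
#'   of the condition has no real logarithm).
#' @export
dt_threshold_ok <- function(params, d1, d2, dt, T = Inf) {
  params <- as_ar_params(params)
  if (d2 <= 0) stop("delta is undefined for 'd2' = 0", call. = FALSE)
  if (d1 < 0 || dt < 0) stop("'d1' and 'dt' must be nonnegative", call. = FALSE)
  if (is.finite(T) && dt >= T) stop("'dt' must be smaller than 'T'", call. = FALSE)
  xi1 <- xi_dose(params, d1)
  fT <- if (is.finite(T)) f_antiderivative(params, d1, T) else 0
  # the condition f(D1, dt) >= -ln(e^{-f(D1,T)} - (D1/D2) e^{-xi}) is
  # evaluated through differences of f inside one exponential, so that it
  # stays exact where the separate exponentials would underflow; it is
  # unsatisfiable (delta < 0 for every gap) iff the ln argument is <= 0,
  # i.e. iff (D1/D2) e^{f(D1,T) - xi} >= 1
  cc <- (d1 / d2) * exp(fT - xi1)
  if (cc >= 1)
    return(list(ok = FALSE, boundary_dt = NA_real_, satisfiable = FALSE))
  g <- function(x) 1 - exp(fT - f_antiderivative(params, d1, x)) - cc
  if (g(0) < 0) {
    boundary <- NA_real_  # even dt = 0 gives delta < 0
  } else {
    upper <- 2 / params$alpha2
    while (g(upper) > 0) upper <- upper * 2
    boundary <- stats::uniroot(g, c(0, upper), tol = 1e-12)$root
  }
  list(ok = g(dt) >= 0, boundary_dt = boundary, satisfiable = TRUE)
}

#' Delta after two priming doses
#'
#' Mutation-endpoint delta when the challenge `d3` follows two priming doses
#' `d1` (at time 0) and `d2` (at `dt1`), with `d3` given `dt2` after `d2`:
#' \deqn{\delta = 1 - e^{-f(D_1,\Delta t_1+\Delta t_2) - f(D_2,\Delta t_2)}
#'  - (D_2/D_3) e^{-f(D_1,\Delta t_1) - \xi_{D_2}}
#'  - (D_1/D_3) e^{-\xi_{D_1} - \xi_{D_2}}.}
#' Reduces to [delta_mutations()] with gap `dt1 + dt2` when `d2 = 0`.
#'
#' @inheritParams delta_lesions
#' @param d3 Challenging dose (Gy), > 0.
#' @param dt1 Gap between the two priming doses (h).
#' @param dt2 Gap between the second priming dose and the challenge (h).
#' @return A `delta_result` object.
#' @export
delta_two_priming <- function(params, d1, d2, d3, dt1, dt2) {
  params <- as_ar_params(params)
  if (any(d3 <= 0)) stop("delta is undefined for 'd3' = 0", call. = FALSE)
  if (any(d1 < 0) || any(d2 < 0)) stop("doses must be nonnegative", call. = FALSE)
  if (any(dt1 < 0) || any(dt2 < 0)) stop("gaps must be nonnegative", call. = FALSE)
  .warn_high_challenge(params, d3)
  f <- function(D, t) f_antiderivative(params, D, t)
  delta <- 1 - exp(-f(d1, dt1 + dt2) - f(d2, dt2)) -
    (d2 / d3) * exp(-f(d1, dt1) - f(d2, 0)) -
    (d1 / d3) * exp(-f(d1, 0) - f(d2, 0))
  new_delta_result(delta, "two_priming",
                   list(params = params, d1 = d1, d2 = d2, d3 = d3,
                        dt1 = dt1, dt2 = dt2))
}

# Survival bookkeeping for an arbitrary train of priming pulses followed by a
# challenge, mutation endpoint. Counts are in units of mu1 (mu-free), so each
# pulse deposits its dose as its lesion count. Returns delta = 1 - N/N_ref;
# the challenge's own repair factor exp(-xi_challenge) cancels in the ratio.
.delta_train <- function(params, doses, times, challenge, challenge_time) {
  n <- length(doses)
  f <- function(D, t) f_antiderivative(params, D, t)
  surv <- doses[1]
  if (n > 1) {
    for (k in 2:n) {
      # decay of the pooled survivors between pulse k-1 and pulse k under all
      # signals already switched on
      i <- seq_len(k - 1)
      decay <- sum(f(doses[i], times[k] - times[i]) -
                     f(doses[i], times[k - 1] - times[i]))
      surv <- doses[k] + surv * exp(decay)
    }
  }
  i <- seq_len(n)
  decay_to_challenge <- sum(f(doses[i], challenge_time - times[i]) -
                              f(doses[i], times[n] - times[i]))
  surv <- surv * exp(decay_to_challenge)
  # from the challenge to T = Inf every f(., Inf) term is 0
  residual <- exp(-sum(f(doses[i], challenge_time - times[i])))
  1 - (challenge + surv) * residual / challenge
}

#' Delta after n identical priming doses ("radiation training")
#'
#' Mutation-endpoint delta when `n` identical priming pulses of
#' `priming_dose`, separated by `dt`, precede a challenge of
#' `challenge_dose` given `dt` after the last pulse. Evaluated by per-dose
#' survival bookkeeping (the nested closed form is the unrolled version of
#' this recursion); for `n = 1` it equals [delta_mutations()] and for
#' `n = 2` it equals [delta_two_priming()] with equal doses and gaps. The
#' chronic limit (`dt -> 0`, `n -> Inf`) is outside this formula's validity;
#' use [chronic_saturation()] for that regime.
#'
#' @inheritParams delta_lesions
#' @param priming_dose Dose of each priming pulse (Gy).
#' @param challenge_dose Challenging dose (Gy), > 0.
#' @param dt Gap between consecutive pulses and before the challenge (h).
#' @param n Number of priming pulses, >= 1.
#' @return A `delta_result` object.
#' @export
delta_multi_priming <- function(params, priming_dose, challenge_dose, dt, n) {
  params <- as_ar_params(params)
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer (delta for n = 0 is 0 by definition)",
         call. = FALSE)
  if (challenge_dose <= 0) stop("delta is undefined for zero challenge dose",
                                call. = FALSE)
  if (priming_dose < 0) stop("'priming_dose' must be nonnegative", call. = FALSE)
  if (dt < 0) stop("'dt' must be nonnegative", call. = FALSE)
  .warn_high_challenge(params, challenge_dose)
  times <- (seq_len(n) - 1) * dt
  delta <- .delta_train(params, rep.int(priming_dose, n), times,
                        challenge_dose, n * dt)
  new_delta_result(delta, "multi_priming",
                   list(params = params, priming_dose = priming_dose,
                        challenge_dose = challenge_dose, dt = dt, n = n))
}
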