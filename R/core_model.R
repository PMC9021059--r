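#' Adaptive-response probability rate after a single dose pulse
#'
#' The probability rate of a successful adaptive-response repair event,
#' \eqn{p_{AR}(D, t) = \alpha_0 D^2 t^2 e^{-\alpha_1 D - \alpha_2 t}}, for a
#' pulse of dose `dose` received `t` hours ago. Vectorised over `dose` and
#' `t`.
#'
#' @param params An [ar_params()] object.
#' @param dose Absorbed dose (Gy), >= 0.
#' @param t Time since the pulse (h), >= 0.
#' @return Probability rate (h^-1).
#' @export
p_ar_pulse <- function(params, dose, t) {
  params <- as_ar_params(params)
  if (any(dose < 0)) stop("'dose' must be nonnegative", call. = FALSE)
  if (any(t < 0)) stop("'t' must be nonnegative", call. = FALSE)
  params$alpha0 * dose^2 * t^2 * exp(-params$alpha1 * dose - params$alpha2 * t)
}

# Antiderivative closed form without argument checks; t may be Inf (-> 0).
# The exponent is always <= 0, so the closed form cannot overflow.
.f_anti <- function(alpha0, alpha1, alpha2, dose, t) {
  out <- (alpha0 / alpha2^3) * dose^2 *
    exp(-alpha1 * dose - alpha2 * t) *
    ((alpha2 * t)^2 + 2 * alpha2 * t + 2)
  out[is.infinite(t) & t > 0] <- 0
  out
}

#' Antiderivative of the repair signal
#'
#' The closed form \eqn{f(D, t) = -\int p_{AR}\,dt =
#' (\alpha_0/\alpha_2^3) D^2 e^{-\alpha_1 D - \alpha_2 t}
#' [(\alpha_2 t)^2 + 2\alpha_2 t + 2]}. `f(D, 0)` equals the lifetime repair
#' integral \eqn{\xi_D} and `f(D, Inf) = 0`; `Inf` is accepted as a
#' first-class value for `t`.
#'
#' @inheritParams p_ar_pulse
#' @return Dimensionless repair potential.
#' @seealso [xi_dose()], [repair_integral()]
#' @export
f_antiderivative <- function(params, dose, t) {
  params <- as_ar_params(params)
  if (any(dose < 0)) stop("'dose' must be nonnegative", call. = FALSE)
  if (any(t < 0)) stop("'t' must be nonnegative", call. = FALSE)
  .f_anti(params$alpha0, params$alpha1, params$alpha2, dose, t)
}

#' Lifetime repair integral of a single pulse
#'
#' \eqn{\xi_D = 2 (\alpha_0/\alpha_2^3) D^2 e^{-\alpha_1 D}}, the total
#' repair accumulated over an infinite horizon from one pulse of dose `D`.
#' Equals `f_antiderivative(params, dose, 0)` and peaks at `D = 2/alpha1`.
#'
#' @inheritParams p_ar_pulse
#' @export
xi_dose <- function(params, dose) {
  params <- as_ar_params(params)
  if (any(dose < 0)) stop("'dose' must be nonnegative", call. = FALSE)
  2 * (params$alpha0 / params$alpha2^3) * dose^2 * exp(-params$alpha1 * dose)
}

#' Repair accumulated over a time interval
#'
#' \eqn{-\int_a^b p_{AR}\,dt = f(D, b) - f(D, a)}; always <= 0 because `f` is
#' nonincreasing in time. `b` may be `Inf`, in which case the value is
#' `-f(D, a)` (and `-xi_dose(params, dose)` for `a = 0`).
#'
#' @inheritParams p_ar_pulse
#' @param a,b Interval bounds in hours, `0 <= a <= b`; `b` may be `Inf`.
#' @export
repair_integral <- function(params, dose, a, b) {
  params <- as_ar_params(params)
  if (any(a < 0)) stop("'a' must be nonnegative", call. = FALSE)
  if (any(a > b)) stop("'a' must not exceed 'b'", call. = FALSE)
  f_antiderivative(params, dose, b) - f_antiderivative(params, dose, a)
}

#' Lesions induced by a dose pulse
#'
#' Linear induction law \eqn{N = \mu_0 + \mu_1 D}.
#'
#' @param mu A [lesion_params()] object.
#' @param dose Absorbed dose (Gy), >= 0.
#' @export
induced_lesions <- function(mu, dose) {
  if (!inherits(mu, "lesion_params")) stop("'mu' must be a lesion_params object",
                                           call. = FALSE)
  if (any(dose < 0)) stop("'dose' must be nonnegative", call. = FALSE)
  mu$mu0 + mu$mu1 * dose
}

#' Unrepaired lesions after a single pulse
#'
#' Solves the repair kinetics \eqn{dN = -N\,p_{AR}\,dt} for one pulse:
#' \eqn{N(T) = N_0 e^{f(D,T) - f(D,0)}}. The count decreases monotonically
#' with `T` but never below \eqn{N_0 e^{-\xi_D}}: repair saturates because
#' the adaptive-response signal decays away.
#'
#' @inheritParams p_ar_pulse
#' @param n0 Initial lesion count, >= 0.
#' @param T Observation time in hours since the pulse; may be `Inf`.
#' @export
lesions_remaining_single <- function(params, n0, dose, T) {
  params <- as_ar_params(params)
  if (any(n0 < 0)) stop("'n0' must be nonnegative", call. = FALSE)
  if (any(T < 0)) stop("'T' must be nonnegative", call. = FALSE)
  n0 * exp(f_antiderivative(params, dose, T) -
             f_antiderivative(params, dose, 0))
}

#' Unrepaired lesions in the priming + challenging scheme
#'
#' Lesion count at observation time `T` when a priming dose `d1` at time 0 is
#' followed by a challenging dose `d2` at time `dt`. The `d1` lesions decay
#' under their own repair signal up to `dt`; from `dt` on, both signals act
#' additively on the pooled lesions:
#' \deqn{N(T) = (N_{0,2} + N_{0,1} e^{f(D_1,\Delta t) - f(D_1,0)})
#'   e^{f(D_1,T) - f(D_1,\Delta t) + f(D_2,T-\Delta t) - f(D_2,0)}.}
#' Initial counts follow the convention \eqn{N_{0,1} = \mu_0 + \mu_1 D_1}
#' and \eqn{N_{0,2} = \mu_1 D_2} (background counted once).
#'
#' Note the zero-gap convention lives in the signal layer: at `dt = 0` the
#' two pulses merge and \eqn{p_{AR}(D_1, D_2, t) = p_{AR}(D_1 + D_2, t)};
#' the count formula above keeps the two signals separate.
#'
#' @inheritParams p_ar_pulse
#' @param mu A [lesion_params()] object.
#' @param d1,d2 Priming and challenging doses (Gy).
#' @param dt Inter-dose interval (h).
#' @param T Observation time (h) on the `d1` clock, `T >= dt`; may be `Inf`.
#' @export
lesions_remaining_two_dose <- function(params, mu, d1, d2, dt, T) {
  params <- as_ar_params(params)
  if (!inherits(mu, "lesion_params")) stop("'mu' must be a lesion_params object",
                                           call. = FALSE)
  if (any(d1 < 0) || any(d2 < 0)) stop("doses must be nonnegative", call. = FALSE)
  if (any(dt < 0)) stop("'dt' must be nonnegative", call. = FALSE)
  if (any(dt > T)) stop("'dt' must not exceed 'T'", call. = FALSE)
  n01 <- mu$mu0 + mu$mu1 * d1
  n02 <- mu$mu1 * d2
  f <- function(D, t) f_antiderivative(params, D, t)
  (n02 + n01 * exp(f(d1, dt) - f(d1, 0))) *
    exp(f(d1, T) - f(d1, dt) + f(d2, T - dt) - f(d2, 0))
}

#' Adaptive-response signal of a discrete pulse schedule
#'
#' Sum of the independent pulse signals
#' \eqn{p_{AR} = \alpha_0 \sum_k D_k^2 (K-k)^2 e^{-\alpha_1 D_k - \alpha_2 (K-k)}}
#' at age step `age_step` (= K). Each pulse contributes the single-pulse term
#' with its own elapsed time; the terms are additive. The physical duration
#' of one step is `step_hours` (default 1 h per step).
#'
#' @inheritParams p_ar_pulse
#' @param schedule A [dose_schedule()] object.
#' @param age_step Current age in steps; all schedule steps must be <= it.
#' @param step_hours Hours per time step.
#' @return Probability rate (h^-1).
#' @export
p_ar_schedule_discrete <- function(params, schedule, age_step, step_hours = 1) {
  params <- as_ar_params(params)
  if (!inherits(schedule, "dose_schedule"))
    stop("'schedule' must be a dose_schedule object", call. = FALSE)
  if (any(schedule$steps > age_step))
    stop("schedule contains a dose after 'age_step'", call. = FALSE)
  elapsed <- (age_step - schedule$steps) * step_hours
  sum(p_ar_pulse(params, schedule$doses, elapsed))
}

#' Adaptive-response signal under continuous irradiation
#'
#' Quadrature of
#' \eqn{p_{AR}(\tau) = \alpha_0 \int_0^\tau \dot D(t)^2 (\tau-t)^2
#' e^{-\alpha_1 \dot D(t) - \alpha_2 (\tau-t)}\,dt}
#' for a nonnegative dose-rate history `dose_rate_fn` (Gy/h). For a constant
#' rate the signal grows monotonically with age and saturates at
#' [chronic_saturation()].
#'
#' @inheritParams p_ar_pulse
#' @param dose_rate_fn A function of time returning the dose rate (Gy/h), or
#'   a single number for a constant rate.
#' @param tau Age (h) at which the signal is evaluated.
#' @param abs.tol Absolute quadrature tolerance.
#' @export
p_ar_continuous <- function(params, dose_rate_fn, tau, abs.tol = 1e-10) {
  params <- as_ar_params(params)
  if (is.numeric(dose_rate_fn) && length(dose_rate_fn) == 1L) {
    rate <- dose_rate_fn
    dose_rate_fn <- function(t) rep.int(rate, length(t))
  }
  if (tau < 0) stop("'tau' must be nonnegative", call. = FALSE)
  if (tau == 0) return(0)
  probe <- dose_rate_fn(seq(0, tau, length.out = 101L))
  if (any(probe < 0)) stop("dose rate must be nonnegative", call. = FALSE)
  integrand <- function(t) {
    dr <- dose_rate_fn(t)
    params$alpha0 * dr^2 * (tau - t)^2 *
      exp(-params$alpha1 * dr - params$alpha2 * (tau - t))
  }
  stats::integrate(integrand, 0, tau, abs.tol = abs.tol,
                   rel.tol = .Machine$double.eps^0.5,
                   subdivisions = 500L)$value
}

#' Saturation signal under chronic constant-rate irradiation
#'
#' The limit of the continuous signal for constant dose rate and large age:
#' \eqn{P_c = (2\alpha_0/\alpha_2^3)\dot D^2 e^{-\alpha_1 \dot D} = \xi_{\dot D}}.
#'
#' @inheritParams p_ar_pulse
#' @param dose_rate Constant dose rate (Gy/h), >= 0.
#' @export
chronic_saturation <- function(params, dose_rate) {
  xi_dose(params, dose_rate)
}
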