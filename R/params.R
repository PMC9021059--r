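#' Adaptive-response parameters
#'
#' Container for the three parameters of the adaptive-response
#' probability-rate \eqn{p_{AR} = \alpha_0 D^2 t^2 e^{-\alpha_1 D - \alpha_2 t}}.
#' All three must be strictly positive; the repair signal then peaks at dose
#' \eqn{D = 2/\alpha_1} and at time \eqn{t = 2/\alpha_2} after exposure.
#'
#' @param alpha0 Rate amplitude, Gy^-2 h^-3.
#' @param alpha1 Dose-decay constant, Gy^-1.
#' @param alpha2 Time-decay constant, h^-1.
#' @return An object of class `ar_params`.
#' @examples
#' ar_params(36.2, 120.2, 0.0845)
#' @export
ar_params <- function(alpha0, alpha1, alpha2) {
  for (nm in c("alpha0", "alpha1", "alpha2")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm),
           call. = FALSE)
  }
  structure(list(alpha0 = alpha0, alpha1 = alpha1, alpha2 = alpha2),
            class = "ar_params")
}

#' @export
print.ar_params <- function(x, ...) {
  cat("Adaptive-response parameters:\n")
  cat(sprintf("  alpha0 = %g Gy^-2 h^-3\n  alpha1 = %g Gy^-1\n  alpha2 = %g h^-1\n",
              x$alpha0, x$alpha1, x$alpha2))
  cat(sprintf("  peak response: D = %.4g Gy, t = %.4g h after exposure\n",
              2 / x$alpha1, 2 / x$alpha2))
  invisible(x)
}

as_ar_params <- function(x) {
  if (inherits(x, "ar_params")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(ar_params(x[1], x[2], x[3]))
  stop("expected an 'ar_params' object or a numeric vector of length 3",
       call. = FALSE)
}

#' Linear lesion-induction parameters
#'
#' Parameters of the linear induction law \eqn{N = \mu_0 + \mu_1 D}: `mu0` is
#' the spontaneous (zero-dose) lesion count and `mu1` the lesions induced per
#' unit dose. Typically \eqn{\mu_0 \ll \mu_1}; the defaults are the published
#' calibration for human lymphocytes.
#'
#' @param mu0 Background lesion count (dimensionless), >= 0.
#' @param mu1 Lesions per unit dose, Gy^-1, > 0.
#' @return An object of class `lesion_params`.
#' @export
lesion_params <- function(mu0 = 0.0005, mu1 = 0.832) {
  if (!is.numeric(mu0) || length(mu0) != 1L || !is.finite(mu0) || mu0 < 0)
    stop("'mu0' must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(mu1) || length(mu1) != 1L || !is.finite(mu1) || mu1 <= 0)
    stop("'mu1' must be a single positive number", call. = FALSE)
  structure(list(mu0 = mu0, mu1 = mu1), class = "lesion_params")
}

#' @export
print.lesion_params <- function(x, ...) {
  cat(sprintf("Lesion induction: N = %g + %g D  [D in Gy]\n", x$mu0, x$mu1))
  invisible(x)
}

#' Pulsed dose schedule
#'
#' An ordered sequence of instantaneous dose pulses given at integer time
#' steps, for the discrete-schedule form of the adaptive-response signal.
#'
#' @param doses Numeric vector of absorbed doses (Gy), all >= 0.
#' @param steps Integer time steps at which the pulses are received;
#'   must be nondecreasing.
#' @return An object of class `dose_schedule`.
#' @export
dose_schedule <- function(doses, steps) {
  if (length(doses) != length(steps))
    stop("'doses' and 'steps' must have equal length", call. = FALSE)
  if (any(doses < 0)) stop("doses must be nonnegative", call. = FALSE)
  if (is.unsorted(steps)) stop("'steps' must be nondecreasing", call. = FALSE)
  structure(list(doses = as.numeric(doses), steps = as.numeric(steps)),
            class = "dose_schedule")
}
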