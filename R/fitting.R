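#' Configuration for parameter estimation
#'
#' Shared settings for the two estimation routes. Bounds default to a box
#' spanning every published estimate by at least two orders of magnitude;
#' both optimisers work on log10-transformed parameters inside that box.
#' The genetic-algorithm budget (population 99, the published population
#' size) is scaled to desk size by default and can be raised to the full
#' published budget (millions of generations, >= 50 restarts) through these
#' fields.
#'
#' @param lower,upper Per-parameter bounds on (alpha0, alpha1, alpha2),
#'   all positive.
#' @param grid_points Points per axis of the log-spaced multistart grid used
#'   by [fit_lbfgsb()].
#' @param maxit Iteration cap per quasi-Newton start.
#' @param population Individuals per genetic-algorithm generation.
#' @param generations Generations per genetic-algorithm run.
#' @param restarts Independent genetic-algorithm runs.
#' @param sigma0,sigma_final Initial and final scale of the multiplicative
#'   log-normal mutation (annealed geometrically across generations).
#' @param keep_tol Runs whose best fitness differs from the overall best by
#'   more than this fraction are discarded.
#' @param refine Brute-force grid refinement of the surviving region after
#'   the genetic-algorithm runs.
#' @param seed Integer seed for the stochastic route.
#' @return A `fit_config` list.
#' @export
fit_config <- function(lower = c(1e-6, 1e-3, 1e-8),
                       upper = c(1e6, 1e4, 10),
                       grid_points = 5L,
                       maxit = 1000L,
                       population = 99L,
                       generations = 600L,
                       restarts = 12L,
                       sigma0 = 0.6,
                       sigma_final = 0.01,
                       keep_tol = 0.01,
                       refine = TRUE,
                       seed = NULL) {
  stopifnot(length(lower) == 3L, length(upper) == 3L,
            all(lower > 0), all(upper > lower),
            population >= 2L, restarts >= 1L, generations >= 1L)
  structure(list(lower = lower, upper = upper, grid_points = grid_points,
                 maxit = maxit, population = as.integer(population),
                 generations = as.integer(generations),
                 restarts = as.integer(restarts), sigma0 = sigma0,
                 sigma_final = sigma_final, keep_tol = keep_tol,
                 refine = refine, seed = seed),
            class = "fit_config")
}

.check_records <- function(records, variant) {
  req <- c("d1_gy", "d2_gy", "dt_h", "delta")
  if (inherits(records, "dataset_bundle")) records <- records$records
  if (!is.data.frame(records) || !all(req %in% names(records)))
    stop("records must contain columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (variant == "lesions") {
    if (!"t_h" %in% names(records) || anyNA(records$t_h))
      stop("the lesions variant needs a finite observation time 't_h' ",
           "in every record", call. = FALSE)
  }
  records
}

#' Least-squares objective of the delta model
#'
#' Sum of squared residuals between observed deltas and the mu-free model:
#' the finite-time lesion form for `variant = "lesions"` and the
#' late-effect mutation form for `variant = "mutations"`. This is the
#' objective both estimation routes minimise; the published fits use its
#' reciprocal as the fitness function.
#'
#' @param params [ar_params()] or numeric length-3 vector.
#' @param records A `dataset_bundle` or data frame with columns `d1_gy`,
#'   `d2_gy`, `dt_h`, `delta` (and `t_h` for the lesion variant).
#' @param variant `"lesions"` or `"mutations"`.
#' @return The sum of squared delta residuals.
#' @export
ssr_objective <- function(params, records, variant = c("lesions", "mutations")) {
  variant <- match.arg(variant)
  records <- .check_records(records, variant)
  if (nrow(records) == 0L) return(0)
  params <- as_ar_params(params)
  model <- if (variant == "lesions") {
    .delta_lesions_kernel(params$alpha0, params$alpha1, params$alpha2,
                          records$d1_gy, records$d2_gy, records$dt_h,
                          records$t_h)
  } else {
    .delta_mutations_kernel(params$alpha0, params$alpha1, params$alpha2,
                            records$d1_gy, records$d2_gy, records$dt_h)
  }
  sum((records$delta - model)^2)
}

# SSR on the log10 scale used inside the optimisers (records pre-validated)
.ssr_log10 <- function(lp, records, variant) {
  a <- 10^lp
  model <- if (variant == "lesions") {
    .delta_lesions_kernel(a[1], a[2], a[3], records$d1_gy, records$d2_gy,
                          records$dt_h, records$t_h)
  } else {
    .delta_mutations_kernel(a[1], a[2], a[3], records$d1_gy, records$d2_gy,
                            records$dt_h)
  }
  s <- sum((records$delta - model)^2)
  if (!is.finite(s)) .Machine$double.xmax else s
}

new_ar_fit <- function(params, ssr, method, records_n, variant, config,
                       restarts = NULL, uncertainty = NULL) {
  structure(list(params = params, ssr = ssr, fitness = 1 / ssr,
                 method = method, n_records = records_n, variant = variant,
                 restarts = restarts, uncertainty = uncertainty,
                 config = config),
            class = "ar_fit")
}

#' @export
print.ar_fit <- function(x, ...) {
  cat(sprintf("Adaptive-response fit (%s, %s variant, %d records)\n",
              x$method, x$variant, x$n_records))
  cat(sprintf("  alpha0 = %.6g Gy^-2 h^-3\n  alpha1 = %.6g Gy^-1\n  alpha2 = %.6g h^-1\n",
              x$params$alpha0, x$params$alpha1, x$params$alpha2))
  cat(sprintf("  SSR = %.8g  (fitness %.6g)\n", x$ssr, x$fitness))
  if (!is.null(x$restarts))
    cat(sprintf("  runs: %d kept / %d total\n",
                x$restarts$kept, x$restarts$total))
  if (!is.null(x$uncertainty)) {
    cat("  Poisson worst-case bounds (offsets from estimate):\n")
    print(x$uncertainty$offsets)
  }
  invisible(x)
}

#' Multistart bounded quasi-Newton fit
#'
#' Minimises [ssr_objective()] over positive (alpha0, alpha1, alpha2) with
#' L-BFGS-B started from every node of a log-spaced grid inside the bounds,
#' keeping the best converged start. Deterministic for a given
#' configuration.
#'
#' @inheritParams ssr_objective
#' @param config A [fit_config()].
#' @param verbose Print the best objective after each improving start.
#' @return An `ar_fit` object.
#' @export
fit_lbfgsb <- function(records, variant = c("lesions", "mutations"),
                       config = fit_config(), verbose = FALSE) {
  variant <- match.arg(variant)
  records <- .check_records(records, variant)
  if (nrow(records) < 3L)
    warning("fewer records than free parameters: the fit is underdetermined",
            call. = FALSE)
  lo <- log10(config$lower); hi <- log10(config$upper)
  axes <- lapply(1:3, function(i) seq(lo[i], hi[i],
                                      length.out = config$grid_points))
  grid <- as.matrix(expand.grid(axes))
  best <- NULL
  n_ok <- 0L
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch(
      stats::optim(grid[i, ], .ssr_log10, records = records,
                   variant = variant, method = "L-BFGS-B",
                   lower = lo, upper = hi,
                   control = list(maxit = config$maxit, factr = 1e5)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1L
    if (is.null(best) || res$value < best$value) {
      best <- res
      if (verbose)
        message(sprintf("start %d: SSR %.8g at (%.4g, %.4g, %.4g)", i,
                        res$value, 10^res$par[1], 10^res$par[2], 10^res$par[3]))
    }
  }
  if (is.null(best))
    stop("all quasi-Newton starts failed", call. = FALSE)
  a <- unname(10^best$par)
  new_ar_fit(ar_params(a[1], a[2], a[3]), best$value, "lbfgsb",
             nrow(records), variant, config,
             restarts = list(total = nrow(grid), kept = n_ok))
}

# one SGA run; A is 3 x population matrix of parameter candidates
.sga_run <- function(records, variant, config) {
  lo <- log(config$lower); hi <- log(config$upper)
  pop <- config$population
  A <- exp(matrix(stats::runif(3 * pop, lo, hi), 3, pop))
  gens <- config$generations
  sig <- config$sigma0 * (config$sigma_final / config$sigma0)^
    (seq_len(gens) / gens)
  ssr_pop <- function(A) {
    R <- nrow(records); P <- ncol(A)
    f <- function(D, t) {
      a0 <- matrix(A[1, ], R, P, byrow = TRUE)
      a1 <- matrix(A[2, ], R, P, byrow = TRUE)
      a2 <- matrix(A[3, ], R, P, byrow = TRUE)
      Dm <- matrix(D, R, P); tm <- matrix(t, R, P)
      (a0 / a2^3) * Dm^2 * exp(-a1 * Dm - a2 * tm) *
        ((a2 * tm)^2 + 2 * a2 * tm + 2)
    }
    if (variant == "lesions") {
      dm <- 1 - exp(f(records$d1_gy, records$t_h) -
                      f(records$d1_gy, records$dt_h)) -
        (records$d1_gy / records$d2_gy) *
          exp(f(records$d1_gy, records$t_h) - f(records$d1_gy, 0))
    } else {
      dm <- 1 - exp(-f(records$d1_gy, records$dt_h)) -
        (records$d1_gy / records$d2_gy) * exp(-f(records$d1_gy, 0))
    }
    s <- colSums((dm - records$delta)^2)
    s[!is.finite(s)] <- .Machine$double.xmax
    s
  }
  best <- Inf; best_par <- NULL
  for (g in seq_len(gens)) {
    s <- ssr_pop(A)
    i <- which.min(s)
    if (s[i] < best) { best <- s[i]; best_par <- A[, i] }
    w <- 1 / s
    idx <- sample.int(pop, pop, replace = TRUE, prob = w / sum(w))
    A <- A[, idx, drop = FALSE] *
      exp(matrix(stats::rnorm(3 * pop, 0, sig[g]), 3, pop))
    A <- pmin(pmax(A, exp(lo)), exp(hi))
    A[, 1] <- best_par  # elitism: the incumbent always survives unmutated
  }
  list(par = best_par, ssr = best)
}

#' Simplified genetic algorithm fit
#'
#' Stochastic global search with fitness-proportional selection (fitness =
#' 1/SSR), no crossover, and small multiplicative log-normal mutations
#' whose scale anneals geometrically across generations; the incumbent best
#' individual always survives. Runs `restarts` independent populations;
#' runs whose fitness differs from the best by more than `keep_tol` are
#' discarded, and the surviving region is optionally refined by a
#' brute-force grid search.
#'
#' @inheritParams fit_lbfgsb
#' @return An `ar_fit` object; `$restarts` records kept/discarded runs.
#' @export
fit_sga <- function(records, variant = c("lesions", "mutations"),
                    config = fit_config(), verbose = FALSE) {
  variant <- match.arg(variant)
  records <- .check_records(records, variant)
  if (nrow(records) < 3L)
    warning("fewer records than free parameters: the fit is underdetermined",
            call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)
  runs <- vector("list", config$restarts)
  for (r in seq_len(config$restarts)) {
    runs[[r]] <- .sga_run(records, variant, config)
    if (verbose)
      message(sprintf("run %d/%d: best SSR %.8g", r, config$restarts,
                      runs[[r]]$ssr))
  }
  ssrs <- vapply(runs, `[[`, numeric(1), "ssr")
  best_ssr <- min(ssrs)
  keep <- (1 / ssrs) >= (1 - config$keep_tol) / best_ssr
  if (!any(keep))
    stop("no genetic-algorithm run survived the fitness filter", call. = FALSE)
  kept_pars <- vapply(runs[keep], `[[`, numeric(3), "par")
  best_par <- runs[[which.min(ssrs)]]$par
  if (isTRUE(config$refine)) {
    # brute-force scan of the box spanned by the surviving runs
    span <- apply(log(kept_pars), 1, range)
    pad <- pmax(0.02, 0.25 * (span[2, ] - span[1, ]))
    axes <- lapply(1:3, function(i)
      seq(span[1, i] - pad[i], span[2, i] + pad[i], length.out = 9L))
    g <- as.matrix(expand.grid(axes))
    vals <- apply(g, 1, function(lp)
      .ssr_log10(lp / log(10), records, variant))
    if (min(vals) < best_ssr) {
      best_ssr <- min(vals)
      best_par <- exp(g[which.min(vals), ])
    }
  }
  best_par <- unname(best_par)
  new_ar_fit(ar_params(best_par[1], best_par[2], best_par[3]), best_ssr,
             "sga", nrow(records), variant, config,
             restarts = list(total = config$restarts, kept = sum(keep),
                             run_ssr = ssrs))
}

#' Poisson worst-case parameter uncertainty
#'
#' Upper-lower bound method: assuming the event counts of both arms follow
#' Poisson laws, two extreme datasets are built by shifting every count by
#' one standard deviation (sqrt of the count) in the directions that
#' maximise delta (challenge arm up, primed arm down) and minimise it
#' (reversed), the model is refitted to each, and per-parameter offsets
#' from the central estimate are reported. Requires raw integer counts with
#' real denominators; frequency-only records are not supported.
#'
#' @inheritParams fit_lbfgsb
#' @param best The central `ar_fit`.
#' @return The `best` fit with an `uncertainty` element: a list with
#'   `offsets` (3 x 2 matrix of lower/upper offsets) and the two extreme
#'   refits.
#' @export
poisson_worstcase_uncertainty <- function(records,
                                          best,
                                          variant = c("lesions", "mutations"),
                                          config = fit_config()) {
  variant <- match.arg(variant)
  records <- .check_records(records, variant)
  cols <- c("n2_events", "n2_denom", "n12_events", "n12_denom")
  if (!all(cols %in% names(records)) || anyNA(records[cols]))
    stop("worst-case bounds need raw event counts in every record",
         call. = FALSE)
  if (any(records$n2_denom <= 1) ||
      any(records$n2_events != round(records$n2_events)))
    stop("frequency-only records (no real denominators) are not supported ",
         "by the Poisson worst-case method", call. = FALSE)
  shift <- function(sign) {
    r <- records
    n2 <- pmax(r$n2_events + sign * sqrt(r$n2_events), 1e-9)
    n12 <- pmax(r$n12_events - sign * sqrt(r$n12_events), 0)
    r$delta <- delta_from_counts(n2, r$n2_denom, n12, r$n12_denom)
    r
  }
  fit_hi <- fit_lbfgsb(shift(+1), variant, config)  # delta pushed up
  fit_lo <- fit_lbfgsb(shift(-1), variant, config)  # delta pushed down
  central <- unlist(best$params)
  extremes <- rbind(unlist(fit_hi$params), unlist(fit_lo$params))
  lower <- pmin(apply(extremes, 2, min), central) - central
  upper <- pmax(apply(extremes, 2, max), central) - central
  offsets <- cbind(lower = lower, upper = upper)
  rownames(offsets) <- c("alpha0", "alpha1", "alpha2")
  best$uncertainty <- list(offsets = offsets, fit_upper_delta = fit_hi,
                           fit_lower_delta = fit_lo)
  best
}

#' Ordinary least-squares trend of delta against a design variable
#'
#' Straight-line fit (closed-form OLS via [stats::lm()]) of one record field
#' against another, as used to summarise how the protective effect decays
#' with the inter-dose interval.
#'
#' @param records A `dataset_bundle` or data frame.
#' @param x,y Column names of the predictor and response.
#' @return List with `slope`, `intercept`, `r_squared`, `n`, and the `lm`
#'   fit.
#' @export
linear_trend <- function(records, x = "dt_h", y = "delta") {
  if (inherits(records, "dataset_bundle")) records <- records$records
  if (!all(c(x, y) %in% names(records)))
    stop("columns not found: ", paste(setdiff(c(x, y), names(records)),
                                      collapse = ", "), call. = FALSE)
  if (nrow(records) < 2L) stop("need at least two points", call. = FALSE)
  if (stats::var(records[[x]]) == 0)
    stop("degenerate predictor: no variance in '", x, "'", call. = FALSE)
  fit <- stats::lm(stats::reformulate(x, y), data = records)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = suppressWarnings(summary(fit)$r.squared),
       n = nrow(records),
       fit = fit)
}

#' Serialise a fit report to JSON
#'
#' @param fit An `ar_fit`.
#' @param path Output path.
#' @param seed Optional seed to record alongside the configuration.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path, seed = NULL) {
  stopifnot(inherits(fit, "ar_fit"))
  report <- list(
    params = unclass(fit$params),
    ssr = fit$ssr,
    fitness = fit$fitness,
    method = fit$method,
    variant = fit$variant,
    n_records = fit$n_records,
    restarts = fit$restarts[c("total", "kept")],
    uncertainty = if (!is.null(fit$uncertainty))
      list(lower = fit$uncertainty$offsets[, "lower"],
           upper = fit$uncertainty$offsets[, "upper"]),
    config = fit$config[c("lower", "upper", "grid_points", "population",
                          "generations", "restarts")],
    seed = seed)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
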