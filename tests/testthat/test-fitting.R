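quick_config <- function(...) fit_config(grid_points = 3L, ...)

test_that("the least-squares objective behaves as an SSR should", {
  p <- ar_params(22.9, 79.5, 0.0832)
  les <- load_bundled("shadley_lesions")
  expect_identical(ssr_objective(p, les$records[0, ], "lesions"), 0)
  # records generated exactly from the model have zero residual at the truth
  rec <- les$records
  rec$delta <- primingdose:::.delta_lesions_kernel(
    p$alpha0, p$alpha1, p$alpha2, rec$d1_gy, rec$d2_gy, rec$dt_h, rec$t_h)
  expect_equal(ssr_objective(p, rec, "lesions"), 0)
  # order invariance
  s1 <- ssr_objective(p, les, "lesions")
  s2 <- ssr_objective(p, les$records[sample.int(23), ], "lesions")
  expect_identical(s1, s2)
  # regression anchor at the published lesion optimum, frozen from an
  # independent row-by-row evaluation of the lesion delta formula
  expect_equal(s1, 0.2077191, tolerance = 1e-6)
  norec <- les$records
  norec$t_h <- NULL
  expect_error(ssr_objective(p, norec, "lesions"), "observation time")
})

test_that("quasi-Newton multistart recovers exact synthetic parameters", {
  truth <- ar_params(36.2, 120.2, 0.0845)
  spec <- synthetic_spec(truth, variant = "lesions", noise = "none")
  bundle <- generate_dataset(spec)
  fit <- fit_lbfgsb(bundle, "lesions", quick_config())
  expect_s3_class(fit, "ar_fit")
  expect_lt(fit$ssr, 1e-8)
  expect_equal(unlist(fit$params), unlist(truth), tolerance = 1e-4)
  # bitwise reproducible under an identical configuration
  fit2 <- fit_lbfgsb(bundle, "lesions", quick_config())
  expect_identical(unlist(fit$params), unlist(fit2$params))
})

test_that("quasi-Newton fit of the lesion records matches the published optimum", {
  les <- load_bundled("shadley_lesions")
  fit <- fit_lbfgsb(les, "lesions")
  expect_equal(fit$params$alpha0, 22.9, tolerance = 0.01)
  expect_equal(fit$params$alpha1, 79.5, tolerance = 0.01)
  expect_equal(fit$params$alpha2, 0.0832, tolerance = 0.01)
  expect_lte(fit$ssr,
             ssr_objective(ar_params(22.9, 79.5, 0.0832), les, "lesions"))
})

test_that("the genetic algorithm drives the residual to zero on clean data", {
  truth <- ar_params(22.9, 79.5, 0.0832)
  bundle <- generate_dataset(synthetic_spec(truth, variant = "lesions",
                                            noise = "none"))
  fit <- fit_sga(bundle, "lesions",
                 fit_config(restarts = 4L, generations = 800L, seed = 7L))
  expect_lt(fit$ssr, 1e-6)
  # reproducible given the seed
  fit2 <- fit_sga(bundle, "lesions",
                  fit_config(restarts = 4L, generations = 800L, seed = 7L))
  expect_identical(unlist(fit$params), unlist(fit2$params))
  expect_lte(fit$restarts$kept, fit$restarts$total)
})

test_that("genetic-algorithm fit of the lesion records lands in the published ranges", {
  les <- load_bundled("shadley_lesions")
  fit <- fit_sga(les, "lesions", fit_config(seed = 2L))
  # published asymmetric uncertainty ranges around (22.9, 79.4, 0.0832)
  expect_gt(fit$params$alpha0, 22.9 - 4.0)
  expect_lt(fit$params$alpha0, 22.9 + 0.5)
  expect_gt(fit$params$alpha1, 79.4 - 11.2)
  expect_lt(fit$params$alpha1, 79.4 + 5.5)
  expect_gt(fit$params$alpha2, 0.0832 - 0.0082)
  expect_lt(fit$params$alpha2, 0.0832 + 0.0093)
  # both algorithms agree within those same ranges
  qn <- fit_lbfgsb(les, "lesions")
  expect_lt(abs(fit$params$alpha0 - qn$params$alpha0), 4.0)
  expect_lt(abs(fit$params$alpha1 - qn$params$alpha1), 11.2)
  expect_lt(abs(fit$params$alpha2 - qn$params$alpha2), 0.0093)
})

test_that("Poisson worst-case bounds bracket the estimate and scale with noise", {
  les <- load_bundled("shadley_lesions")
  central <- fit_lbfgsb(les, "lesions")
  with_unc <- poisson_worstcase_uncertainty(les$records, central, "lesions")
  off <- with_unc$uncertainty$offsets
  expect_true(all(off[, "lower"] <= 0))
  expect_true(all(off[, "upper"] >= 0))
  # same order of magnitude as the published (-4.0/+0.5, -11.2/+5.5,
  # -0.0082/+0.0093) spans
  span <- off[, "upper"] - off[, "lower"]
  published_span <- c(4.5, 16.7, 0.0175)
  expect_true(all(span / published_span > 0.1))
  expect_true(all(span / published_span < 10))

  # near-noiseless counts (huge denominators) collapse the bounds
  truth <- ar_params(22.9, 79.5, 0.0832)
  spec <- synthetic_spec(truth, variant = "lesions", noise = "none")
  big <- generate_dataset(spec)
  big$records$n2_denom <- big$records$n12_denom <- 1e9
  big$records$n2_events <- round(big$records$n2_events /
                                   load_bundled("shadley_lesions")$records$n2_denom * 1e9)
  big$records$n12_events <- round((1 - big$records$delta) *
                                    big$records$n2_events)
  big$records$delta <- delta_from_counts(big$records$n2_events, 1e9,
                                         big$records$n12_events, 1e9)
  cfg <- quick_config()
  central_big <- fit_lbfgsb(big$records, "lesions", cfg)
  unc_big <- poisson_worstcase_uncertainty(big$records, central_big,
                                           "lesions", cfg)
  rel_span <- (unc_big$uncertainty$offsets[, "upper"] -
                 unc_big$uncertainty$offsets[, "lower"]) /
    unlist(central_big$params)
  expect_true(all(rel_span < 0.05))

  # frequency-only data carry no Poisson counts to perturb
  day <- load_bundled("day_inversions")
  expect_error(
    poisson_worstcase_uncertainty(day$records, central, "mutations"),
    "not supported")
})

test_that("the mutation-endpoint fit is exercised on the inversion data", {
  day <- load_bundled("day_inversions")
  spleen <- day$records[day$records$tissue == "spleen", ]
  # two records for three parameters: underdetermined by design
  expect_warning(fit <- fit_lbfgsb(spleen, "mutations",
                                   fit_config(grid_points = 7L)),
                 "underdetermined")
  printed <- ar_params(11160, 1400.9, 0.0116)
  expect_lte(fit$ssr, ssr_objective(printed, spleen, "mutations") + 1e-9)
})

test_that("the delta-versus-gap trend matches the published line", {
  les <- load_bundled("shadley_lesions")
  sub <- les$records[les$records$study == "Shadley et al.", ]
  expect_identical(nrow(sub), 16L)
  tr <- linear_trend(sub)
  expect_lt(abs(tr$slope - (-0.005)), 5e-4)
  expect_lt(abs(tr$intercept - 0.487), 5e-3)
  expect_lt(abs(tr$r_squared - 0.60), 0.02)
  # two points are interpolated exactly
  two <- data.frame(dt_h = c(1, 3), delta = c(0.2, 0.4))
  tr2 <- linear_trend(two)
  expect_equal(tr2$slope, 0.1)
  expect_equal(tr2$r_squared, 1)
  # a flat response has zero slope
  flat <- data.frame(dt_h = 1:5, delta = rep(0.3, 5))
  expect_equal(linear_trend(flat)$slope, 0)
  expect_error(linear_trend(data.frame(dt_h = c(2, 2), delta = c(1, 2))),
               "degenerate")
})

test_that("fit reports serialise to JSON", {
  les <- load_bundled("shadley_lesions")
  fit <- fit_lbfgsb(les, "lesions", quick_config())
  tmp <- withr::local_tempfile(fileext = ".json")
  write_fit_report(fit, tmp, seed = 1L)
  rep <- jsonlite::read_json(tmp, simplifyVector = TRUE)
  expect_equal(rep$params$alpha0, fit$params$alpha0)
  expect_equal(rep$ssr, fit$ssr)
  expect_identical(rep$seed, 1L)
})
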