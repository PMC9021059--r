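test_that("pulse signal matches its closed form and peaks where expected", {
  p <- example_params()
  expect_identical(p_ar_pulse(p, 0, 5), 0)
  expect_equal(p_ar_pulse(p, 1, 3), 9 * exp(-3.1))
  expect_equal(p_ar_pulse(p, 1, 3), 0.405442821542, tolerance = 1e-10)
  # the maximum over t sits at 2/alpha2 and over D at 2/alpha1
  for (i in 1:5) {
    q <- random_params()
    tgrid <- seq(1e-3, 10 / q$alpha2, length.out = 2000)
    expect_equal(tgrid[which.max(p_ar_pulse(q, 1, tgrid))], 2 / q$alpha2,
                 tolerance = 1e-2)
    dgrid <- seq(1e-3, 10 / q$alpha1, length.out = 2000)
    expect_equal(dgrid[which.max(p_ar_pulse(q, dgrid, 1))], 2 / q$alpha1,
                 tolerance = 1e-2)
  }
  expect_error(p_ar_pulse(p, -1, 2), "nonnegative")
  expect_error(p_ar_pulse(p, 1, -2), "nonnegative")
})

test_that("antiderivative agrees with quadrature and has the right limits", {
  p <- example_params()
  expect_identical(f_antiderivative(p, 1, Inf), 0)
  expect_equal(f_antiderivative(p, 1, 0), xi_dose(p, 1))
  expect_equal(xi_dose(p, 1), 2.14506962782, tolerance = 1e-10)
  expect_equal(f_antiderivative(p, 1, 3), 1.3935044822, tolerance = 1e-9)
  # f(D, t) equals the tail integral of the pulse signal
  expect_equal(f_antiderivative(p, 1, 3), -quad_repair(p, 1, 3, Inf),
               tolerance = 1e-8)
  expect_identical(xi_dose(p, 0), 0)
})

test_that("interval repair integral matches adaptive quadrature", {
  p <- example_params()
  expect_identical(repair_integral(p, 1, 2, 2), 0)
  expect_equal(repair_integral(p, 1, 0, Inf), -xi_dose(p, 1))
  expect_equal(repair_integral(p, 1, 0, 3), -0.751565145619, tolerance = 1e-9)
  expect_error(repair_integral(p, 1, 3, 2), "exceed")
  set.seed(11)
  for (i in 1:200) {
    q <- random_params()
    D <- stats::runif(1, 0, 3)
    a <- stats::runif(1, 0, 5)
    b <- a + stats::runif(1, 0, 10)
    val <- repair_integral(q, D, a, b)
    expect_equal(val, quad_repair(q, D, a, b),
                 tolerance = 1e-8 / (1 + abs(val)))
  }
})

test_that("the antiderivative differentiates back to the pulse signal", {
  set.seed(21)
  h <- 1e-5
  for (i in 1:20) {
    q <- random_params()
    D <- stats::runif(1, 0.1, 2)
    tgrid <- seq(0.5, 4 / q$alpha2, length.out = 9)
    deriv <- -(f_antiderivative(q, D, tgrid + h) -
                 f_antiderivative(q, D, tgrid - h)) / (2 * h)
    expect_equal(deriv, p_ar_pulse(q, D, tgrid), tolerance = 1e-6)
  }
})

test_that("linear lesion induction behaves", {
  mu <- lesion_params(0.0005, 0.832)
  expect_equal(induced_lesions(mu, 0), 0.0005)
  expect_equal(induced_lesions(mu, 1), 0.8325)
  mu0 <- lesion_params(0, 2)
  expect_equal(induced_lesions(mu0, c(1, 2.5)), c(2, 5))
  expect_error(lesion_params(-1, 1), "nonnegative")
  expect_error(lesion_params(0, 0), "positive")
})

test_that("single-pulse repair kinetics decay monotonically to the floor", {
  p <- example_params()
  expect_equal(lesions_remaining_single(p, 100, 1, 0), 100)
  expect_equal(lesions_remaining_single(p, 100, 1, Inf),
               100 * exp(-xi_dose(p, 1)))
  expect_equal(lesions_remaining_single(p, 100, 1, 3), 47.1627808572,
               tolerance = 1e-9)
  set.seed(31)
  for (i in 1:10) {
    q <- random_params()
    Tgrid <- seq(0, 20 / q$alpha2, length.out = 50)
    n <- lesions_remaining_single(q, 50, 1.2, Tgrid)
    expect_true(all(diff(n) <= 1e-12))
    expect_true(all(n >= 50 * exp(-xi_dose(q, 1.2)) - 1e-12))
  }
  expect_error(lesions_remaining_single(p, -1, 1, 2), "nonnegative")
})

test_that("two-dose kinetics reduce correctly and match the chained oracle", {
  p <- example_params()
  mu <- lesion_params(0, 1)
  # no priming dose and no background: the challenge repairs on its own clock
  expect_equal(lesions_remaining_two_dose(p, mu, 0, 5, 3, 10),
               lesions_remaining_single(p, induced_lesions(mu, 5), 5, 7))
  # at T = dt the challenge's own repair has not started yet
  expect_equal(lesions_remaining_two_dose(p, mu, 1, 5, 3, 3),
               5 + 1 * exp(f_antiderivative(p, 1, 3) - xi_dose(p, 1)))
  expect_equal(lesions_remaining_two_dose(p, mu, 1, 5, 3, Inf),
               0.508578174916, tolerance = 1e-9)
  expect_error(lesions_remaining_two_dose(p, mu, 1, 5, 3, 2), "exceed")
  expect_error(lesions_remaining_two_dose(p, mu, -1, 5, 3, 9), "nonnegative")
})

test_that("discrete schedules add pulse signals and merge at zero gap", {
  p <- example_params()
  expect_identical(p_ar_schedule_discrete(p, dose_schedule(1, 5), 5), 0)
  expect_equal(p_ar_schedule_discrete(p, dose_schedule(1, 2), 5),
               p_ar_pulse(p, 1, 3))
  s2 <- dose_schedule(c(0.5, 1.5), c(1, 3))
  expect_equal(p_ar_schedule_discrete(p, s2, 7),
               p_ar_pulse(p, 0.5, 6) + p_ar_pulse(p, 1.5, 4))
  # zero-gap convention: two simultaneous pulses act as their sum
  expect_equal(p_ar_pulse(p, 1 + 2, 4), p_ar_pulse(p, 3, 4))
  expect_error(p_ar_schedule_discrete(p, dose_schedule(1, 9), 5), "after")
  # the step duration scales elapsed time
  expect_equal(p_ar_schedule_discrete(p, dose_schedule(1, 2), 5,
                                      step_hours = 0.5),
               p_ar_pulse(p, 1, 1.5))
})

test_that("continuous irradiation converges to the chronic saturation level", {
  p <- example_params()
  expect_identical(p_ar_continuous(p, 0, 50), 0)
  expect_equal(chronic_saturation(p, 0.5), 0.884155480631, tolerance = 1e-9)
  expect_equal(p_ar_continuous(p, 0.5, 50), chronic_saturation(p, 0.5),
               tolerance = 1e-4)
  # monotone approach to the plateau beyond the signal peak
  taus <- c(5, 10, 20, 40)
  vals <- vapply(taus, function(tt) p_ar_continuous(p, 0.5, tt), numeric(1))
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals < chronic_saturation(p, 0.5) + 1e-10))
  set.seed(41)
  for (i in 1:5) {
    q <- random_params()
    dr <- stats::runif(1, 0.1, 1)
    expect_equal(chronic_saturation(q, dr), xi_dose(q, dr))
  }
  expect_error(p_ar_continuous(p, function(t) -t, 10), "nonnegative")
})
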