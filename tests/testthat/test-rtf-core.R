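test_that("time transformation matches its defining formula and limits", {
  # t = 0 cancels both log terms exactly, for any tau
  for (tau in c(-3, 0, 0.3, 7)) {
    expect_identical(rtf_transform_time(0, tau, 5), 0)
  }
  # tau -> -inf limit: the transformation becomes t * 10 / t_range
  expect_equal(rtf_transform_time(5, -12, 5), 10, tolerance = 1e-8)
  expect_equal(rtf_transform_time(7, -12, 7), 10, tolerance = 1e-8)
  # direct evaluation: exponent 10 * 1 / 10 = 1
  expect_equal(rtf_transform_time(1, 0, 10), log10(5.5), tolerance = 1e-12)
  # stable for exponents far beyond double overflow
  expect_true(is.finite(rtf_transform_time(400, 0, 10)))
  expect_true(is.finite(rtf_transform_time(1, 400, 10)))
  expect_error(rtf_transform_time(NA_real_, 0, 10), "non-finite")
  expect_error(rtf_transform_time(1, 0, 0), "t_range")
})

test_that("time transformation is bounded and monotone", {
  taus <- seq(-3, 3, length.out = 13)
  ts <- seq(0, 12, length.out = 25)
  for (tau in taus) {
    v <- rtf_transform_time(ts, tau, 10)
    expect_true(all(v >= 0))
    expect_true(all(v <= 10 * ts / 10 + 1e-12))
    expect_true(all(diff(v) > 0))  # monotone increasing in t
  }
  # non-increasing in tau at fixed t
  for (t in c(0.5, 3, 9)) {
    v <- vapply(taus, function(tau) rtf_transform_time(t, tau, 10), numeric(1))
    expect_true(all(diff(v) <= 1e-12))
  }
})

test_that("Hill function reproduces half-maximal point and direct values", {
  expect_equal(rtf_hill(3, M = 2, K = 3, h = 5), 1)            # d = K: M/2
  expect_equal(rtf_hill(3, M = 3, K = 2, h = 4), 243 / 97)     # direct
  expect_equal(rtf_hill(0, M = 1, K = 1, h = 2,
                        direction = "decreasing"), 1)          # d = 0: M
  expect_equal(rtf_hill(0, M = 1, K = 1, h = 2), 0)
  # K = 0 conventions: increasing is constant M, decreasing constant 0
  expect_equal(rtf_hill(c(0, 1, 5), M = 2, K = 0, h = 3), rep(2, 3))
  expect_equal(rtf_hill(c(0, 1, 5), M = 2, K = 0, h = 3,
                        direction = "decreasing"), rep(0, 3))
  expect_error(rtf_hill(-1, M = 1, K = 1, h = 1), "dose")
})

test_that("Hill function is monotone and bounded by M", {
  d <- seq(0, 50, length.out = 101)
  for (M in c(2, -1.5)) {
    up <- rtf_hill(d, M, K = 4, h = 2.5)
    dn <- rtf_hill(d, M, K = 4, h = 2.5, direction = "decreasing")
    if (M > 0) {
      expect_true(all(diff(up) > 0) && all(up >= 0 & up <= M))
      expect_true(all(diff(dn) < 0) && all(dn >= 0 & dn <= M))
    } else {
      expect_true(all(diff(up) < 0) && all(up <= 0 & up >= M))
    }
  }
})

test_that("single-dose RTF matches closed-form values and asymptotics", {
  # t = 0 always returns the offset exactly
  p <- rtf_params(A = 2, B = 1, alpha = 0.5, beta = 2, gamma = 0.3,
                  tau = 0.7, b = 1.25)
  expect_identical(rtf_curve(0, p, 10), 1.25)
  # sustained-only curve at transformed time ~ 2 (tau = -12 makes the
  # transformation essentially linear, 10 * t / t_range)
  p2 <- rtf_params(A = 2, B = 0, alpha = 0.5, beta = 1, gamma = 1,
                   tau = -12, b = 1)
  expect_equal(rtf_curve(2, p2, 10), 2 * (1 - exp(-1)) + 1, tolerance = 1e-8)
  # full two-component curve at transformed time ~ 1
  p3 <- rtf_params(A = 1, B = 2, alpha = 1, beta = 2, gamma = 0.5,
                   tau = -12, b = 0)
  expect_equal(rtf_curve(1, p3, 10),
               1 - exp(-1) + 2 * (1 - exp(-2)) * exp(-0.5), tolerance = 1e-7)
  # late-time plateau at A + b for gamma > 0
  expect_equal(rtf_curve(1e6 * 10, p, 10), p$A + p$b, tolerance = 1e-6 * p$A)
  expect_error(rtf_params(A = 1, B = 1, alpha = -1, beta = 1, gamma = 1,
                          tau = 0, b = 0), "rate")
})

test_that("dose resolution evaluates each parameter through its triplet", {
  dp <- rtf_dose_params(A = rtf_hill_triplet(4, 1, 1),
                        B = rtf_hill_triplet(2, 1, 1),
                        alpha = rtf_hill_triplet(1, 1, 1),
                        beta = rtf_hill_triplet(1.5, 1, 1),
                        gamma = rtf_hill_triplet(0.5, 1, 1),
                        tau = rtf_hill_triplet(2, 1, 1),
                        b = 0.3, sigma = 0.1)
  # direct value: 4 * 3 / (1 + 3) = 3
  expect_equal(rtf_params_at_dose(dp, 3)$A, 3)
  # d = K for every triplet, equal h: every dynamic parameter at half-max
  at_K <- rtf_params_at_dose(dp, 1)
  expect_equal(at_K$A, 2); expect_equal(at_K$tau, 1)
  expect_equal(at_K$alpha, 0.5); expect_equal(at_K$b, 0.3)
  # b and sigma pass through unchanged
  expect_identical(at_K$sigma, 0.1)
})

test_that("all K = 0 collapses the dose-dependent RTF to the single-dose RTF", {
  dp <- rtf_dose_params(A = 1.2, B = 0.5, alpha = 0.9, beta = 1.4,
                        gamma = 0.4, tau = 0.7, b = 0.1, sigma = 1)
  p <- rtf_params(A = 1.2, B = 0.5, alpha = 0.9, beta = 1.4, gamma = 0.4,
                  tau = 0.7, b = 0.1)
  for (d in c(0.1, 1, 2, 50)) {
    at <- rtf_params_at_dose(dp, d)
    expect_identical(unlist(at), unlist(p))
    expect_equal(rtf_curve_dose(seq(0, 10, 0.5), d, dp, 10),
                 rtf_curve(seq(0, 10, 0.5), p, 10), tolerance = 1e-15)
  }
})

test_that("dose-dependent RTF equals the oracle composition on a grid", {
  dp <- rtf_dose_params(A = rtf_hill_triplet(2, 3, 2),
                        B = rtf_hill_triplet(1, 2, 1.5),
                        alpha = rtf_hill_triplet(0.9, 4, 3),
                        beta = rtf_hill_triplet(1.8, 3, 2),
                        gamma = rtf_hill_triplet(0.6, 5, 2),
                        tau = rtf_hill_triplet(1.5, 2.5, 2),
                        b = 0.2, sigma = 0.1)
  ts <- c(0, 1, 2.5, 6, 10)
  for (d in c(0.5, 3, 8)) {
    expect_equal(rtf_curve_dose(ts, d, dp, 10),
                 oracle_dose_rtf(ts, d, dp, 10), tolerance = 1e-13)
  }
  # response at t = 0 is b at every dose
  expect_equal(rtf_curve_dose(0, 4, dp, 10), 0.2)
})

test_that("fold-changes multiply exactly the named scalars", {
  dp <- rtf_dose_params(A = rtf_hill_triplet(1.5, 4, 2), B = 0,
                        alpha = rtf_hill_triplet(1, 3, 2), beta = 1, gamma = 1,
                        tau = 0.5, b = 0, sigma = 0.1)
  # identity: all deltas 1
  expect_identical(rtf_apply_fold_changes(dp, c(M_A = 1, K_A = 1, tau = 1)), dp)
  out <- rtf_apply_fold_changes(dp, c(M_A = 2, K_A = 0.5))
  expect_equal(out$A$M, 3)
  expect_equal(out$A$K, 2)
  # every other field untouched
  out$A <- dp$A
  expect_identical(out, dp)
  # bare name addresses the constant value of a plain parameter
  expect_equal(rtf_apply_fold_changes(dp, c(tau = 3))$tau$M, 1.5)
  expect_error(rtf_apply_fold_changes(dp, c(M_A = 0)), "> 0")
  expect_error(rtf_apply_fold_changes(dp, c(M_X = 2)), "unknown")
})

test_that("free-parameter accounting matches the model algebra", {
  full <- c("A", "B", "alpha", "beta", "gamma", "tau")
  expect_identical(n_free_parameters(rtf_spec(dose_dependent = full,
                                              ties = NULL)), 20L)
  expect_identical(n_free_parameters(spec_joint()), 11L)
  expect_identical(n_free_parameters(rtf_spec(fixed_to_zero = "B"),
                                     n_doses = 7), 35L)
  expect_identical(n_free_parameters(rtf_spec(ties = NULL)), 8L)
  # default ties: beta and gamma mirror alpha -> one shared rate
  expect_identical(n_free_parameters(rtf_spec()), 6L)
  # condition dependencies add one delta per scalar per extra condition
  s2 <- rtf_spec(dose_dependent = c("A", "alpha", "tau"), fixed_to_zero = "B",
                 conditions = c("wt", "ko"),
                 condition_dependent = c("M_A", "K_alpha", "h_tau"))
  expect_identical(n_free_parameters(s2), 14L)
  s3 <- rtf_spec(dose_dependent = "A", fixed_to_zero = "B",
                 conditions = c("wt", "ko1", "ko2"),
                 condition_dependent = c("M_A", "alpha"))
  expect_identical(n_free_parameters(s3), 11L)
  # tie to a removed parameter is a spec error
  expect_error(rtf_spec(fixed_to_zero = "B", ties = c(alpha = "gamma")),
               "fixed to zero")
  expect_error(n_free_parameters(spec_joint(), n_doses = 3),
               "without dose dependencies")
})
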