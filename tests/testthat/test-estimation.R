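test_that("default bounds implement the documented formulas", {
  d <- data.frame(time = rep(0:10, 2), dose = rep(1:2, each = 11),
                  condition = "all", replicate = 1,
                  value = c(seq(0, 1, length.out = 11),
                            seq(0, 1, length.out = 11)))
  sp <- rtf_bounds(d, rtf_spec(dose_dependent = "A", fixed_to_zero = "B",
                               ties = NULL))
  row <- function(nm) sp[sp$name == nm, ]
  # y in [0, 1], times 0..10 step 1
  expect_equal(unlist(row("M_A")[, c("lower", "upper")]),
               c(lower = 0, upper = 2))
  expect_equal(unlist(row("tau")[, c("lower", "upper", "init")]),
               c(lower = -2, upper = 5, init = -1))
  expect_equal(unlist(row("alpha")[, c("lower", "upper")]),
               c(lower = 0.05, upper = 2))
  expect_equal(unlist(row("h_A")[, c("lower", "upper")]), c(lower = 1, upper = 10))
  expect_equal(unlist(row("b")[, c("lower", "upper")]), c(lower = 0, upper = 1))
  expect_equal(row("M_A")$init, 1.8)           # 0.1 lb + 0.9 ub
  expect_equal(row("sigma")$upper, sd(d$value))
  # dose ladder 1..7 -> K bounds [0.1, 70]
  d2 <- data.frame(time = rep(0:10, 7), dose = rep(1:7, each = 11),
                   condition = "all", replicate = 1, value = runif(77))
  sp2 <- rtf_bounds(d2, rtf_spec(dose_dependent = "A", fixed_to_zero = "B"))
  expect_equal(unlist(sp2[sp2$name == "K_A", c("lower", "upper")]),
               c(lower = 0.1, upper = 70))
  # down-regulation flips the amplitude box
  spd <- rtf_bounds(d, rtf_spec(fixed_to_zero = "B", sign = c(A = "down")))
  expect_equal(unlist(spd[spd$name == "A", c("lower", "upper")]),
               c(lower = -2, upper = 0))
  # delta fold-changes span two orders of magnitude around 1
  d3 <- d; d3$condition <- rep(c("wt", "ko"), each = 11)
  sp3 <- rtf_bounds(d3, rtf_spec(fixed_to_zero = "B",
                                 conditions = c("wt", "ko"),
                                 condition_dependent = "A"))
  expect_equal(unlist(sp3[sp3$name == "delta_A",
                          c("lower", "upper", "init")]),
               c(lower = 1e-2, upper = 1e2, init = 1))
  expect_equal(sp3[sp3$name == "delta_A", "scale"], "log10")
})

test_that("bounds reject degenerate designs", {
  d <- data.frame(time = rep(c(0, 0, 0, 1, 2), 2), dose = 1, condition = "all",
                  replicate = 1, value = rnorm(10))
  expect_error(rtf_bounds(data.frame(time = rep(1, 5), dose = 1,
                                     condition = "all", replicate = 1,
                                     value = rnorm(5)),
                          rtf_spec(fixed_to_zero = "B")),
               "time points")
  expect_error(rtf_bounds(d, rtf_spec(dose_dependent = "A",
                                      fixed_to_zero = "B")),
               "2 distinct doses")
})

test_that("log-likelihood and chi-square match their closed forms", {
  # constant model: predictions equal b everywhere
  d <- data.frame(time = c(0, 1, 2), dose = 1, condition = "all",
                  replicate = 1, value = c(0.5, 0.5, 0.5))
  spec <- rtf_spec(fixed_to_zero = "B", ties = NULL)
  th0 <- c(A = 0, alpha = 1, tau = 0, b = 0.5, sigma = 1)
  # zero residuals, sigma 1: -N/2 log(2 pi)
  expect_equal(rtf_loglik(th0, d, spec), -3 / 2 * log(2 * pi))
  # one point with residual 1
  d1 <- d; d1$value <- c(0.5, 0.5, 1.5)
  expect_equal(rtf_loglik(th0, d1, spec) - rtf_loglik(th0, d, spec) * 2 / 3,
               -0.5 * log(2 * pi) - 0.5)
  # widening sigma at zero residuals strictly lowers the likelihood
  th2 <- th0; th2["sigma"] <- 2
  expect_lt(rtf_loglik(th2, d, spec), rtf_loglik(th0, d, spec))
  expect_error(rtf_loglik(replace(th0, 5, -1), d, spec), "sigma")
  # chi-square: residuals (1, 2) at sigma 1 and 2
  d2 <- d; d2$value <- c(0.5, 1.5, 2.5)
  expect_equal(rtf_chisq(th0, d2, spec, sigma_fixed = 1), 5)
  expect_equal(rtf_chisq(th0, d2, spec, sigma_fixed = 2), 1.25)
  expect_equal(rtf_chisq(th0, d, spec, sigma_fixed = 1), 0)
})

test_that("start sampling is deterministic, anchored, and uniform", {
  d <- simulate_inflammasome(seed = 7, knockout = FALSE, n_replicates = 1)
  sp <- rtf_bounds(d, spec_joint())
  # single start is exactly the default initial guess (optimization scale)
  s1 <- rtf_starts(sp, 1)
  expect_equal(drop(s1), setNames(rtfit:::to_scale(sp$init, sp$scale), sp$name))
  # determinism under a fixed seed
  expect_identical(rtf_starts(sp, 20, seed = 5), rtf_starts(sp, 20, seed = 5))
  # marginals approximately uniform on the sampling scale
  s <- rtf_starts(sp, 201, seed = 3)[-1, ]
  for (nm in c("M_A", "K_A", "sigma")) {
    i <- match(nm, sp$name)
    lo <- rtfit:::to_scale(sp$lower, sp$scale)[i]
    hi <- rtfit:::to_scale(sp$upper, sp$scale)[i]
    ks <- suppressWarnings(ks.test(s[, nm], "punif", lo, hi))
    expect_lt(unname(ks$statistic), 0.15)
  }
})

test_that("noise-free single-dose data are recovered almost exactly", {
  p <- rtf_dose_params(A = 1.4, B = 0, alpha = 0.7, beta = 0.7, gamma = 0.7,
                       tau = 0.9, b = 0.2, sigma = 1)
  d <- simulate_timecourse(p, doses = 1, times = seq(0, 10, length.out = 9),
                           n_replicates = 2, sigma = 0)
  spec <- rtf_spec(fixed_to_zero = "B")
  fit <- rtf(d, spec, n_starts = 6, seed = 2)
  est <- coef(fit)
  expect_lt(abs(est["A"] - 1.4) / 1.4, 0.01)
  expect_lt(abs(est["alpha"] - 0.7) / 0.7, 0.01)
  expect_lt(abs(est["tau"] - 0.9) / 0.9, 0.01)
  expect_lt(abs(est["b"] - 0.2) / 0.2, 0.01)
  # stationarity: refitting from the optimum does not move the likelihood
  x_hat <- matrix(rtfit:::to_scale(fit$theta, fit$space$scale),
                  nrow = 1, dimnames = list(NULL, fit$space$name))
  refit <- rtf(d, spec, starts = x_hat)
  expect_lt(abs(refit$logLik - fit$logLik), 1e-6)
})

test_that("fitting respects bounds and beats the generating parameters", {
  d <- simulate_inflammasome(seed = 3, knockout = FALSE)
  fit <- rtf(d, spec_joint(), n_starts = 6, seed = 3)
  sp <- fit$space
  expect_true(all(coef(fit) >= sp$lower[!sp$fixed] - 1e-12))
  expect_true(all(coef(fit) <= sp$upper[!sp$fixed] + 1e-12))
  truth <- c(M_A = 1, K_A = 4, h_A = 2, M_alpha = 0.8, K_alpha = 3,
             h_alpha = 2, M_tau = 2, K_tau = 5, h_tau = 2, b = 0.05,
             sigma = attr(d, "sigma"))
  expect_gte(fit$logLik, rtf_loglik(truth, d, fit$spec))
  # waterfall: non-decreasing, anchored at the reported optimum
  wf <- waterfall(fit)
  expect_true(all(diff(wf$objective) >= 0))
  expect_equal(wf$objective[1], -fit$logLik)
  expect_identical(nrow(wf), 6L)
})

test_that("K = 0 constrained dose model reproduces the single-dose fit", {
  p <- rtf_dose_params(A = 1.1, B = 0, alpha = 0.6, beta = 0.6, gamma = 0.6,
                       tau = 0.8, b = 0.1, sigma = 1)
  # truth has no dose dependency, so both model structures are equivalent
  d <- simulate_timecourse(p, doses = c(2, 4), times = seq(0, 10, length.out = 8),
                           n_replicates = 2, sigma = 0.03, seed = 9)
  # single-dose fit
  f1 <- rtf(d, rtf_spec(fixed_to_zero = "B"), n_starts = 5, seed = 1)
  # dose-dependent structure with every K pinned to 0 (and h, irrelevant)
  spec2 <- spec_joint()
  sp2 <- rtf_bounds(d, spec2)
  sp2 <- fix_parameters(sp2, c(K_A = 0, h_A = 1, K_alpha = 0, h_alpha = 1,
                               K_tau = 0, h_tau = 1))
  f2 <- rtf(d, spec2, space = sp2, n_starts = 5, seed = 1)
  expect_lt(abs(f1$logLik - f2$logLik), 1e-4)
})

test_that("single fitted sigma tracks the generating noise level", {
  d <- simulate_inflammasome(seed = 5, knockout = FALSE)
  fit <- rtf(d, spec_joint(), n_starts = 6, seed = 5)
  expect_lt(abs(coef(fit)["sigma"] - attr(d, "sigma")) / attr(d, "sigma"), 0.25)
  expect_lt(abs(sd(residuals(fit)) - attr(d, "sigma")) / attr(d, "sigma"), 0.25)
})

test_that("analytic likelihood gradient matches central finite differences", {
  check_grad <- function(data, spec, seed) {
    plan <- rtfit:::rtf_model_plan(data, spec)
    sp <- rtf_bounds(data, spec)
    y <- data$value
    nll <- function(th) -sum(dnorm(y, plan$predict(th), th[plan$isigma],
                                   log = TRUE))
    set.seed(seed)
    th <- runif(nrow(sp), sp$lower, pmin(sp$upper, 12))
    th[grep("^delta", sp$name)] <- runif(sum(grepl("^delta", sp$name)),
                                         0.3, 3)
    th[match("sigma", sp$name)] <- 0.05
    ga <- plan$grad_nll(th, y)
    gn <- vapply(seq_along(th), function(k) {
      e <- max(1e-7, abs(th[k]) * 1e-6)
      tp <- th; tm <- th
      tp[k] <- th[k] + e; tm[k] <- th[k] - e
      (nll(tp) - nll(tm)) / (2 * e)
    }, numeric(1))
    max(abs(ga - gn) / pmax(abs(gn), 1e-4))
  }
  # two-condition model with fold-changes on M, K and h scalars
  d2 <- simulate_inflammasome(seed = 3)
  s2 <- spec_joint(conditions = c("wildtype", "knockout"),
                   condition_dependent = c("M_A", "K_A", "h_alpha", "M_tau"))
  expect_lt(check_grad(d2, s2, seed = 11), 1e-4)
  # single condition, transient component present, beta/gamma tied to alpha
  d1 <- simulate_inflammasome(seed = 4, knockout = FALSE)
  s1 <- rtf_spec(dose_dependent = c("A", "B", "alpha", "tau"))
  expect_lt(check_grad(d1, s1, seed = 12), 1e-4)
})
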