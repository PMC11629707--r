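# Independent oracle implementations and shared fixtures for the tests.
# These re-derive model values directly from the defining formulas, without
# going through the package's evaluation plan.

# direct formula composition: Hill dose resolution + time transformation +
# sustained/transient response (K > 0 triplets only)
oracle_dose_rtf <- function(t, d, dp, t_range) {
  hill_up <- function(tr) tr$M * d^tr$h / (tr$K^tr$h + d^tr$h)
  hill_down <- function(tr) tr$M * (1 - d^tr$h / (tr$K^tr$h + d^tr$h))
  A <- hill_up(dp$A); B <- hill_up(dp$B)
  alpha <- hill_up(dp$alpha); beta <- hill_up(dp$beta)
  gamma <- hill_up(dp$gamma); tau <- hill_down(dp$tau)
  tt <- log10(10^(t * 10 / t_range) + 10^tau) - log10(1 + 10^tau)
  A * (1 - exp(-alpha * tt)) + B * (1 - exp(-beta * tt)) * exp(-gamma * tt) +
    dp$b
}

# the sustained-only dose-dependent truth used across estimation tests
# (same parameter values as the shipped synthetic fixture generator)
wt_truth <- function(sigma = 0.017) {
  rtf_dose_params(A = rtf_hill_triplet(1, 4, 2), B = 0,
                  alpha = rtf_hill_triplet(0.8, 3, 2), beta = 0.8, gamma = 0.8,
                  tau = rtf_hill_triplet(2, 5, 2), b = 0.05, sigma = sigma)
}

fixture_doses <- c(1, 2, 3, 4, 5, 6, 10)
fixture_times <- c(0, 1, 2, 3, 4, 6, 8, 10)

spec_joint <- function(...) {
  rtf_spec(dose_dependent = c("A", "alpha", "tau"), fixed_to_zero = "B", ...)
}

# flat-response dataset with known mean and noise SD, for analytic
# profile-likelihood checks: the model reduces to y ~ N(b, sigma^2)
constant_toy <- function(seed, n_times = 8, n_rep = 3, mean = 0.5, sd = 0.1) {
  set.seed(seed)
  data.frame(time = rep(seq(0, 10, length.out = n_times), n_rep),
             dose = 1, condition = "all",
             replicate = rep(seq_len(n_rep), each = n_times),
             value = rnorm(n_times * n_rep, mean, sd))
}

# space in which only the offset b is free (A pinned at 0, sigma known)
constant_toy_space <- function(d, sd = 0.1) {
  spec <- rtf_spec(fixed_to_zero = "B", ties = NULL)
  sp <- rtf_bounds(d, spec)
  fix_parameters(sp, c(A = 0, alpha = 1, tau = 0, sigma = sd))
}
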