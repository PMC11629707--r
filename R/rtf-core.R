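#' Retarded time transformation
#'
#' Maps real measurement times onto the transformed time axis on which the
#' RTF exponentials act.  The transformation
#' \deqn{t(t_{real}, \tau) = \log_{10}(10^{t_{real} \cdot 10 / T} + 10^{\tau})
#'       - \log_{10}(1 + 10^{\tau})}
#' rescales the measurement window to roughly \eqn{[0, 10]} (making the model
#' independent of time units) and delays the onset of the response by the
#' time-shift \eqn{\tau}: larger \eqn{\tau} means a later response.
#'
#' Both log-sum terms are evaluated in a log-sum-exp-stable form, so the
#' function does not overflow for large \code{t * 10 / t_range} or large
#' \code{|tau|}.
#'
#' @param t numeric vector of real times (same units as the data).
#' @param tau time shift, in transformed-time units; may be negative.
#' @param t_range positive scalar, the range \code{max(time) - min(time)} of
#'   the dataset the curve is fitted to.
#' @return numeric vector of transformed times; 0 at \code{t = 0}, bounded
#'   above by \code{10 * t / t_range}, monotone increasing in \code{t} and
#'   non-increasing in \code{tau}.
#' @examples
#' rtf_transform_time(c(0, 1, 5, 10), tau = 0.5, t_range = 10)
#' @export
rtf_transform_time <- function(t, tau, t_range) {
  if (!all(is.finite(t)) || !all(is.finite(tau)) || !is.finite(t_range))
    stop("non-finite input to rtf_transform_time()")
  if (t_range <= 0) stop("'t_range' must be > 0")
  a <- t * 10 / t_range
  # log10(10^a + 10^tau) computed as m + log10(10^(a-m) + 10^(tau-m))
  m1 <- pmax(a, tau)
  m0 <- pmax(0, tau)
  (m1 + log10(10^(a - m1) + 10^(tau - m1))) -
    (m0 + log10(10^(-m0) + 10^(tau - m0)))
}

#' Hill dose-response function
#'
#' The increasing form \eqn{M d^h / (K^h + d^h)} and the decreasing form
#' \eqn{M (1 - d^h / (K^h + d^h))} used for the dose dependencies of the RTF
#' dynamic parameters (the decreasing form is used for the time shift, which
#' shrinks as the dose grows).
#'
#' At \code{K = 0} the ratio \eqn{d^h/(K^h+d^h)} equals 1 for every
#' \eqn{d > 0}, so the increasing form is the constant \code{M} and the
#' decreasing form is the constant 0; the ambiguous point \code{d = 0,
#' K = 0} is defined by the same constants.  Note that at the model level
#' (see [rtf_params_at_dose()]) \code{K = 0} is interpreted as "no dose
#' dependency" and yields the constant \code{M} for both directions.
#'
#' @param d dose(s), must be >= 0.
#' @param M maximum value (units of the governed parameter; may be negative
#'   for down-regulated amplitudes).
#' @param K half-maximal dose (EC50), >= 0, in dose units.
#' @param h Hill coefficient, > 0 (steepness).
#' @param direction `"increasing"` or `"decreasing"`.
#' @return numeric vector of parameter values, in \code{[0, M]}
#'   (or \code{[M, 0]} for negative \code{M}).
#' @examples
#' rtf_hill(3, M = 2, K = 3, h = 5)            # half-maximal point: M/2
#' rtf_hill(0, M = 1, K = 1, h = 2, direction = "decreasing")
#' @export
rtf_hill <- function(d, M, K, h, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  if (any(d < 0)) stop("dose 'd' must be >= 0")
  if (K < 0) stop("'K' must be >= 0")
  if (h <= 0) stop("'h' must be > 0")
  # d^h/(K^h + d^h), with the 0/0 point at d = K = 0 resolved to 1
  frac <- ifelse(d == 0 & K == 0, 1, d^h / (K^h + d^h))
  if (direction == "increasing") M * frac else M * (1 - frac)
}

#' Evaluate the single-dose RTF
#'
#' The response curve
#' \deqn{R(t) = A (1 - e^{-\alpha t'}) +
#'              B (1 - e^{-\beta t'}) e^{-\gamma t'} + b}
#' with \eqn{t'} the retarded transformed time of [rtf_transform_time()].
#' The first term is the sustained component saturating at amplitude
#' \eqn{A}; the second is the transient component with amplitude \eqn{B},
#' rise rate \eqn{\beta} and decay rate \eqn{\gamma}; \eqn{b} is the signal
#' offset.  At \code{t = 0} the curve equals \code{b} exactly; for
#' \eqn{\gamma > 0} it tends to \eqn{A + b} as \eqn{t \to \infty}.
#'
#' @param t numeric vector of real times.
#' @param pars named list or numeric vector with elements `A`, `B`, `alpha`,
#'   `beta`, `gamma`, `tau`, `b` (rates must be positive; see
#'   [rtf_params()]).
#' @param t_range dataset time range, > 0.
#' @return numeric vector of expected responses.
#' @examples
#' p <- rtf_params(A = 1, B = 2, alpha = 1, beta = 2, gamma = 0.5,
#'                 tau = 0, b = 0)
#' rtf_curve(seq(0, 10, 2), p, t_range = 10)
#' @export
rtf_curve <- function(t, pars, t_range) {
  pars <- rtf_params(A = pars[["A"]], B = pars[["B"]], alpha = pars[["alpha"]],
                     beta = pars[["beta"]], gamma = pars[["gamma"]],
                     tau = pars[["tau"]], b = pars[["b"]],
                     sigma = if (!is.null(pars[["sigma"]])) pars[["sigma"]] else 1)
  tt <- rtf_transform_time(t, pars$tau, t_range)
  pars$A * (1 - exp(-pars$alpha * tt)) +
    pars$B * (1 - exp(-pars$beta * tt)) * exp(-pars$gamma * tt) +
    pars$b
}

#' Single-dose RTF parameter set
#'
#' Validating constructor for the eight quantities of the time-dependent
#' RTF: amplitudes `A` (sustained) and `B` (transient), rate constants
#' `alpha` (sustained), `beta` (transient rise) and `gamma` (transient
#' decay), time shift `tau`, offset `b` and measurement-error SD `sigma`.
#'
#' @param A,B amplitudes (response units); may be negative for
#'   down-regulation.
#' @param alpha,beta,gamma rate constants (> 0, per transformed-time unit).
#' @param tau time shift (transformed-time units; may be negative).
#' @param b offset (response units).
#' @param sigma measurement-error SD (> 0, response units).
#' @return a named list of class `"rtf_params"`.
#' @export
rtf_params <- function(A, B, alpha, beta, gamma, tau, b, sigma = 1) {
  v <- list(A = A, B = B, alpha = alpha, beta = beta, gamma = gamma,
            tau = tau, b = b, sigma = sigma)
  if (any(!vapply(v, function(x) is.numeric(x) && length(x) == 1 && is.finite(x),
                  logical(1))))
    stop("all RTF parameters must be finite numeric scalars")
  if (alpha <= 0 || beta <= 0 || gamma <= 0)
    stop("rate constants 'alpha', 'beta', 'gamma' must be > 0")
  if (sigma <= 0) stop("'sigma' must be > 0")
  structure(v, class = "rtf_params")
}

#' Hill triplet
#'
#' One (M, K, h) triplet describing the dose dependency of a single dynamic
#' RTF parameter.  `K = 0` encodes "no dose dependency": the parameter is
#' then the constant `M` at every dose.
#'
#' @param M maximum value.
#' @param K half-maximal dose, >= 0.  Default 0 (constant parameter).
#' @param h Hill coefficient, > 0.  Default 1; irrelevant when `K = 0`.
#' @return a named list of class `"rtf_hill_triplet"`.
#' @export
rtf_hill_triplet <- function(M, K = 0, h = 1) {
  if (!is.finite(M) || !is.finite(K) || !is.finite(h))
    stop("non-finite Hill triplet")
  if (K < 0) stop("'K' must be >= 0")
  if (h <= 0) stop("'h' must be > 0")
  structure(list(M = M, K = K, h = h), class = "rtf_hill_triplet")
}

#' Dose-dependent RTF parameter set
#'
#' One Hill triplet per dynamic parameter (`A`, `B`, `alpha`, `beta`,
#' `gamma`, `tau`) plus the dose-independent offset `b` and error SD
#' `sigma`.  The time shift `tau` follows the decreasing Hill form (delay
#' shrinks with dose); all other parameters follow the increasing form.
#'
#' @param A,B,alpha,beta,gamma,tau Hill triplets (see [rtf_hill_triplet()]);
#'   plain numbers are promoted to constant triplets (`K = 0`).
#' @param b offset.
#' @param sigma error SD, > 0.
#' @return a named list of class `"rtf_dose_params"`.
#' @examples
#' dp <- rtf_dose_params(A = rtf_hill_triplet(1, K = 4, h = 2),
#'                       B = 0, alpha = 0.8, beta = 0.8, gamma = 0.8,
#'                       tau = rtf_hill_triplet(2, K = 5, h = 2),
#'                       b = 0.05, sigma = 0.02)
#' rtf_params_at_dose(dp, d = 4)
#' @export
rtf_dose_params <- function(A, B, alpha, beta, gamma, tau, b, sigma = 1) {
  as_triplet <- function(x, what) {
    if (inherits(x, "rtf_hill_triplet")) return(x)
    if (is.numeric(x) && length(x) == 1) return(rtf_hill_triplet(x))
    stop("'", what, "' must be a Hill triplet or a scalar")
  }
  tr <- list(A = as_triplet(A, "A"), B = as_triplet(B, "B"),
             alpha = as_triplet(alpha, "alpha"), beta = as_triplet(beta, "beta"),
             gamma = as_triplet(gamma, "gamma"), tau = as_triplet(tau, "tau"))
  if (!is.finite(b)) stop("'b' must be finite")
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  structure(c(tr, list(b = b, sigma = sigma)), class = "rtf_dose_params")
}

#' Resolve dose-dependent parameters at a single dose
#'
#' Evaluates each dynamic parameter's Hill triplet at dose `d` (the time
#' shift through the decreasing form, everything else through the increasing
#' form) and returns the resulting single-dose parameter set.  A triplet
#' with `K = 0` has no dose dependency and contributes the constant `M`,
#' whatever its direction; this is the degeneracy by which the
#' dose-dependent RTF with all `K = 0` collapses to the single-dose RTF with
#' parameter values given by the `M`s.
#'
#' @param dp an [rtf_dose_params()] object.
#' @param d a single dose, >= 0.
#' @return an [rtf_params()] object.
#' @export
rtf_params_at_dose <- function(dp, d) {
  stopifnot(inherits(dp, "rtf_dose_params"), length(d) == 1)
  if (d < 0) stop("dose 'd' must be >= 0")
  at <- function(tr, direction) {
    if (tr$K == 0) tr$M else rtf_hill(d, tr$M, tr$K, tr$h, direction)
  }
  rtf_params(A = at(dp$A, "increasing"),
             B = at(dp$B, "increasing"),
             alpha = at(dp$alpha, "increasing"),
             beta = at(dp$beta, "increasing"),
             gamma = at(dp$gamma, "increasing"),
             tau = at(dp$tau, "decreasing"),
             b = dp$b, sigma = dp$sigma)
}

#' Evaluate the dose-dependent RTF
#'
#' Composition of [rtf_params_at_dose()] and [rtf_curve()]: the expected
#' response at real time `t` under dose `d`.
#'
#' @inheritParams rtf_params_at_dose
#' @param t numeric vector of real times.
#' @param t_range dataset time range, > 0.
#' @return numeric vector of expected responses.
#' @export
rtf_curve_dose <- function(t, d, dp, t_range) {
  rtf_curve(t, rtf_params_at_dose(dp, d), t_range)
}

#' Apply condition fold-changes to a reference parameter set
#'
#' A non-reference biological condition is parameterized relative to the
#' reference by multiplicative fold-changes \eqn{\Delta > 0} on named
#' scalars of the reference set (`"M_A"`, `"K_alpha"`, `"h_tau"`, ...; the
#' plain names `"A"`, `"tau"`, ... address the `M` of a constant parameter).
#' Scalars without a fold-change are shared between conditions;
#' \eqn{\Delta = 1} means no condition effect.
#'
#' @param dp reference-condition [rtf_dose_params()].
#' @param fold_changes named numeric vector or list of fold-changes, all
#'   > 0.
#' @return an [rtf_dose_params()] object for the non-reference condition.
#' @examples
#' dp <- rtf_dose_params(A = rtf_hill_triplet(1.5, 4, 2), B = 0, alpha = 1,
#'                       beta = 1, gamma = 1, tau = 0.5, b = 0, sigma = 0.1)
#' ko <- rtf_apply_fold_changes(dp, c(M_A = 2, tau = 1.5))
#' @export
rtf_apply_fold_changes <- function(dp, fold_changes) {
  stopifnot(inherits(dp, "rtf_dose_params"))
  fc <- unlist(fold_changes)
  if (length(fc) == 0) return(dp)
  if (is.null(names(fc)) || any(!nzchar(names(fc))))
    stop("fold-changes must be named")
  if (any(!is.finite(fc)) || any(fc <= 0))
    stop("all fold-changes must be finite and > 0")
  out <- dp
  for (nm in names(fc)) {
    loc <- .fc_target(nm)
    if (is.na(loc$param) || !loc$param %in% c("A", "B", "alpha", "beta", "gamma", "tau"))
      stop("unknown fold-change target: '", nm, "'")
    out[[loc$param]][[loc$field]] <- out[[loc$param]][[loc$field]] * fc[[nm]]
  }
  out
}

# "M_A" -> (A, M); "K_alpha" -> (alpha, K); bare "tau" -> (tau, M)
.fc_target <- function(nm) {
  if (grepl("^(M|K|h)_", nm)) {
    list(field = sub("_.*$", "", nm), param = sub("^[MKh]_", "", nm))
  } else {
    list(field = "M", param = nm)
  }
}

#' @export
print.rtf_params <- function(x, ...) {
  cat("Single-dose RTF parameters:\n")
  print(unlist(x), ...)
  invisible(x)
}

#' @export
print.rtf_dose_params <- function(x, ...) {
  cat("Dose-dependent RTF parameters (M, K, h per dynamic parameter):\n")
  m <- t(vapply(x[c("A", "B", "alpha", "beta", "gamma", "tau")],
                function(tr) c(M = tr$M, K = tr$K, h = tr$h), numeric(3)))
  print(m, ...)
  cat("b =", x$b, "  sigma =", x$sigma, "\n")
  invisible(x)
}
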