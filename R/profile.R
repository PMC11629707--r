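#' Profile likelihood of fitted parameters
#'
#' For each requested parameter, steps away from its maximum-likelihood
#' estimate in both directions on the parameter's optimization scale
#' (log10 for strictly positive parameters), re-optimizing all remaining
#' free parameters at every step, until the profile log-likelihood has
#' dropped well below the confidence threshold \eqn{LL^* -
#' \chi^2_{1}(level)/2} or a bound of the parameter space is reached.  The
#' step size adapts to keep the per-step log-likelihood change near 0.1;
#' each re-optimization is warm-started from the previous grid point.  Grid
#' points whose re-optimization fails are recorded as gaps and profiling
#' continues.
#'
#' @param fitted an [rtf()] fit.
#' @param which character vector of free parameter names to profile
#'   (default: all free parameters).
#' @param level confidence level for the reported interval (default 0.95).
#'   The profile itself is always traced a margin beyond the corresponding
#'   threshold, far enough that intervals up to the 99\% level can be read
#'   from it.
#' @param max_steps maximum grid points per direction (default 100).
#' @param target_dll desired per-step drop in log-likelihood (default 0.1).
#' @param ... unused.
#' @return for a single parameter an object of class `"rtf_profile"`; for
#'   several, a named list of them with class `"rtf_profiles"`.  Each holds
#'   the grid (`value` on the linear scale, `logLik`), the MLE, the
#'   optimum log-likelihood, and the confidence interval with
#'   open-endpoint flags.
#' @export
profile.rtf_fit <- function(fitted, which = NULL, level = 0.95,
                            max_steps = 100, target_dll = 0.1, ...) {
  space <- fitted$space
  free <- space[!space$fixed, , drop = FALSE]
  if (is.null(which)) which <- free$name
  bad <- setdiff(which, free$name)
  if (length(bad))
    stop("not free parameter(s) of this fit: ", paste(bad, collapse = ", "))
  out <- lapply(which, function(p)
    profile_one(fitted, p, level, max_steps, target_dll))
  names(out) <- which
  if (length(out) == 1) out[[1]]
  else structure(out, class = "rtf_profiles")
}

profile_one <- function(fit, param, level, max_steps, target_dll) {
  space <- fit$space
  plan <- rtf_model_plan(fit$data, fit$spec, t_range = fit$t_range)
  free_idx <- which(!space$fixed)
  free_names <- space$name[free_idx]
  scales <- space$scale
  theta_full <- space$init
  theta_full[free_idx] <- fit$coefficients[free_names]
  pi_free <- match(param, free_names)
  p_scale <- scales[free_idx][pi_free]
  lo <- to_scale(space$lower, scales)[free_idx]
  hi <- to_scale(space$upper, scales)[free_idx]
  y <- plan$data$value
  isig <- plan$isigma

  nll_at <- function(x_all_free) {
    th <- theta_full
    th[free_idx] <- from_scale(x_all_free, scales[free_idx])
    mu <- plan$predict(th)
    if (any(!is.finite(mu))) return(1e10)
    ll <- sum(stats::dnorm(y, mu, th[isig], log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }
  ln10 <- log(10)
  log_free <- scales[free_idx] == "log10"
  grad_at <- function(x_all_free) {
    th <- theta_full
    th[free_idx] <- from_scale(x_all_free, scales[free_idx])
    g <- plan$grad_nll(th, y)[free_idx]
    g[log_free] <- g[log_free] * th[free_idx][log_free] * ln10
    if (any(!is.finite(g))) g[] <- 0
    g
  }

  x_mle <- to_scale(theta_full[free_idx], scales[free_idx])
  others <- setdiff(seq_along(free_names), pi_free)
  reopt <- function(xp, warm) {
    if (length(others) == 0) return(list(ll = -nll_at(xp), warm = warm))
    obj <- function(xo) {
      x <- numeric(length(free_names))
      x[pi_free] <- xp; x[others] <- xo
      nll_at(x)
    }
    gr <- function(xo) {
      x <- numeric(length(free_names))
      x[pi_free] <- xp; x[others] <- xo
      grad_at(x)[others]
    }
    # L-BFGS-B with a deep correction history handles the ill-conditioned
    # ridge left by the profiled parameter far better than a short-memory
    # quasi-Newton here
    r <- tryCatch(stats::optim(warm, obj, gr, method = "L-BFGS-B",
                               lower = lo[others], upper = hi[others],
                               control = list(maxit = 300, lmm = 20,
                                              factr = 1e5)),
                  error = function(e) NULL)
    if (is.null(r)) list(ll = NA_real_, warm = warm)
    else list(ll = -r$value, warm = r$par)
  }

  ll_opt <- fit$logLik
  thr <- stats::qchisq(level, 1) / 2
  stop_drop <- max(thr, stats::qchisq(0.99, 1) / 2) + 0.5
  span <- hi[pi_free] - lo[pi_free]
  step0 <- span / 50

  trace_dir <- function(dir) {
    xs <- lls <- numeric(0)
    xp <- x_mle[pi_free]
    warm <- x_mle[others]
    step <- step0
    prev_ll <- ll_opt
    step_min <- step0 / 256
    for (k in seq_len(max_steps)) {
      # take a step; if it overshoots (large LL drop), halve and retry so
      # the threshold crossing stays tightly bracketed for interpolation
      repeat {
        xp_next <- xp + dir * step
        at_bound <- FALSE
        if (xp_next <= lo[pi_free]) { xp_next <- lo[pi_free]; at_bound <- TRUE }
        if (xp_next >= hi[pi_free]) { xp_next <- hi[pi_free]; at_bound <- TRUE }
        r <- reopt(xp_next, warm)
        overshoot <- !is.na(r$ll) && (prev_ll - r$ll) > 5 * target_dll &&
          step > step_min && !at_bound
        if (!overshoot) break
        step <- max(step / 4, step_min)
      }
      xs <- c(xs, xp_next); lls <- c(lls, r$ll)
      xp <- xp_next
      if (!is.na(r$ll)) {
        warm <- r$warm
        dll <- prev_ll - r$ll
        prev_ll <- r$ll
        if (dll < target_dll / 3) step <- min(step * 2, span / 5)
        if (ll_opt - r$ll > stop_drop) break
      }
      if (at_bound) break
    }
    list(x = xs, ll = lls, at_bound = at_bound)
  }

  left <- trace_dir(-1)
  right <- trace_dir(+1)
  grid_x <- c(rev(left$x), x_mle[pi_free], right$x)
  grid_ll <- c(rev(left$ll), ll_opt, right$ll)
  keep <- !is.na(grid_ll)

  prof <- structure(list(
    parameter = param, level = level, scale = p_scale,
    mle = unname(fit$coefficients[param]),
    mle_scaled = unname(x_mle[pi_free]),
    optimum_logLik = ll_opt, threshold = thr,
    grid = data.frame(value_scaled = grid_x[keep],
                      value = from_scale(grid_x[keep], p_scale),
                      logLik = grid_ll[keep]),
    bounds = c(lower = space$lower[space$name == param],
               upper = space$upper[space$name == param]),
    hit_bound = c(lower = left$at_bound, upper = right$at_bound)),
    class = "rtf_profile")
  ci <- confint(prof, level = level)
  prof$lower <- ci[1]; prof$upper <- ci[2]
  prof$lower_open <- attr(ci, "open")[1]
  prof$upper_open <- attr(ci, "open")[2]
  prof
}

#' Profile-likelihood confidence interval
#'
#' Inverts a profile at the threshold \eqn{LL^* - \chi^2_1(level)/2}
#' (1.9207 log-likelihood units at 95\%), interpolating linearly between
#' adjacent grid points on the profiling scale.  If the profile never drops
#' below the threshold on one side before hitting a bound of the parameter
#' space, the interval is reported as open on that side, with the bound as
#' the endpoint.
#'
#' @param object an `"rtf_profile"`.
#' @param parm unused (a profile concerns a single parameter).
#' @param level confidence level; defaults to the level the profile was
#'   computed for (any level up to 0.99 is supported by the traced grid).
#' @param ... unused.
#' @return numeric vector `c(lower, upper)` on the linear parameter scale
#'   with attribute `"open"` (two logicals).
#' @export
confint.rtf_profile <- function(object, parm = NULL, level = NULL, ...) {
  if (is.null(level)) level <- object$level
  thr_ll <- object$optimum_logLik - stats::qchisq(level, 1) / 2
  g <- object$grid
  below_mle <- g$value_scaled <= object$mle_scaled
  ci <- c(NA_real_, NA_real_); open <- c(FALSE, FALSE)
  for (side in 1:2) {
    gs <- if (side == 1) g[below_mle, , drop = FALSE]
          else g[g$value_scaled >= object$mle_scaled, , drop = FALSE]
    # order outward from the MLE
    ord <- order(gs$value_scaled, decreasing = (side == 1))
    gs <- gs[ord, , drop = FALSE]
    cross <- which(gs$logLik < thr_ll)
    if (length(cross) == 0) {
      # threshold never crossed: open interval ending at the space bound
      ci[side] <- unname(object$bounds[side])
      open[side] <- TRUE
    } else {
      i <- cross[1]
      if (i == 1) {
        ci[side] <- gs$value_scaled[1]
      } else {
        x1 <- gs$value_scaled[i - 1]; x2 <- gs$value_scaled[i]
        l1 <- gs$logLik[i - 1]; l2 <- gs$logLik[i]
        ci[side] <- x1 + (thr_ll - l1) / (l2 - l1) * (x2 - x1)
      }
      ci[side] <- from_scale(ci[side], object$scale)
    }
  }
  structure(ci, open = open, names = c("lower", "upper"))
}

#' @export
confint.rtf_profiles <- function(object, parm = NULL, level = NULL, ...) {
  if (!is.null(parm)) object <- object[parm]
  rows <- lapply(object, function(p) {
    ci <- confint(p, level = level)
    data.frame(parameter = p$parameter, estimate = p$mle,
               lower = ci[1], upper = ci[2],
               lower_open = attr(ci, "open")[1],
               upper_open = attr(ci, "open")[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Profile-likelihood confidence intervals of a fit
#'
#' Convenience wrapper: profiles the requested parameters (see
#' [profile.rtf_fit()]) and inverts each profile at the requested level.
#'
#' @param object an [rtf()] fit.
#' @param parm parameter names (default: all free).
#' @param level confidence level.
#' @param ... passed to [profile.rtf_fit()].
#' @return data frame with one row per parameter: estimate, lower, upper,
#'   open-endpoint flags.
#' @export
confint.rtf_fit <- function(object, parm = NULL, level = 0.95, ...) {
  pr <- profile(object, which = parm, level = level, ...)
  if (inherits(pr, "rtf_profile")) pr <- structure(list(pr), class = "rtf_profiles")
  confint(pr, level = level)
}

#' Likelihood-ratio test of nested RTF models
#'
#' \eqn{LR = 2 (LL_{full} - LL_{nested})}, clipped at zero, referred to a
#' chi-square distribution with `df` degrees of freedom (the number of
#' constrained parameters).  A nested log-likelihood exceeding the full one
#' by more than 1e-6 triggers a warning, as it indicates an optimizer
#' failure in the full fit.
#'
#' @param nested,full [rtf()] fits (or bare log-likelihood values).
#' @param df degrees-of-freedom difference; inferred from the two fits'
#'   free-parameter counts when both are fit objects.
#' @return an object of class `"htest"` with `statistic`, `parameter`
#'   (df) and `p.value`.
#' @export
lrt <- function(nested, full, df = NULL) {
  ll_n <- if (inherits(nested, "rtf_fit")) nested$logLik else as.numeric(nested)
  ll_f <- if (inherits(full, "rtf_fit")) full$logLik else as.numeric(full)
  if (is.null(df)) {
    if (!inherits(nested, "rtf_fit") || !inherits(full, "rtf_fit"))
      stop("'df' must be given unless both arguments are rtf fits")
    df <- full$n_free - nested$n_free
  }
  if (df < 1) stop("'df' must be >= 1")
  if (ll_f < ll_n - 1e-6)
    warning("full model has lower log-likelihood than the nested one; ",
            "the full fit likely did not converge")
  stat <- max(0, 2 * (ll_f - ll_n))
  structure(list(statistic = c(LR = stat), parameter = c(df = df),
                 p.value = stats::pchisq(stat, df, lower.tail = FALSE),
                 method = "Likelihood ratio test of nested RTF models",
                 data.name = "nested vs. full fit"),
            class = "htest")
}

#' Significance of a condition fold-change
#'
#' Decides whether a fold-change parameter \eqn{\Delta} differs
#' significantly from 1 (equivalently, whether \eqn{\log\Delta = 0} is
#' rejected): the null is rejected exactly when 1 lies outside the
#' profile-likelihood confidence interval for \eqn{\Delta}, which is
#' equivalent to a likelihood-ratio test at the corresponding level.  A
#' profile that stays above the threshold on both sides (interval open at
#' both bounds) marks the fold-change as unidentifiable and not
#' significant.
#'
#' @param prof an `"rtf_profile"` of a `delta_*` parameter (profiled on the
#'   log scale).
#' @param level confidence level (default: the profile's level).
#' @return a list of class `"rtf_fc_test"`: `parameter`, `estimate`,
#'   `lower`, `upper`, open flags, `significant`, `unidentifiable`.
#' @export
test_fold_change <- function(prof, level = NULL) {
  stopifnot(inherits(prof, "rtf_profile"))
  if (!startsWith(prof$parameter, "delta_"))
    stop("'", prof$parameter, "' is not a fold-change parameter")
  if (is.null(level)) level <- prof$level
  ci <- confint(prof, level = level)
  open <- attr(ci, "open")
  unident <- all(open)
  inside <- 1 >= ci[1] && 1 <= ci[2]
  structure(list(parameter = prof$parameter,
                 estimate = prof$mle,
                 lower = unname(ci[1]), upper = unname(ci[2]),
                 lower_open = open[1], upper_open = open[2],
                 level = level,
                 significant = !unident && !inside,
                 unidentifiable = unident),
            class = "rtf_fc_test")
}

#' @export
print.rtf_fc_test <- function(x, ...) {
  cat("Fold-change test for ", x$parameter, ": estimate ",
      format(x$estimate, digits = 4), ", ", round(100 * x$level), "% CI [",
      format(x$lower, digits = 4), if (x$lower_open) " (open)" else "", ", ",
      format(x$upper, digits = 4), if (x$upper_open) " (open)" else "", "]\n",
      sep = "")
  cat(if (x$unidentifiable) "  unidentifiable (profile flat)\n"
      else if (x$significant) "  significant: fold-change differs from 1\n"
      else "  not significant: no evidence for a condition effect\n")
  invisible(x)
}

#' @export
print.rtf_profile <- function(x, ...) {
  cat("Profile likelihood for ", x$parameter, " (", nrow(x$grid),
      " grid points, ", round(100 * x$level), "% CI)\n", sep = "")
  cat("  MLE ", format(x$mle, digits = 5), ", CI [",
      format(x$lower, digits = 5), if (x$lower_open) " (open)" else "", ", ",
      format(x$upper, digits = 5), if (x$upper_open) " (open)" else "", "]\n",
      sep = "")
  invisible(x)
}

#' @export
plot.rtf_profile <- function(x, ...) {
  g <- x$grid
  logx <- identical(x$scale, "log10")
  plot(g$value, g$logLik, type = "b", pch = 19, cex = 0.5,
       log = if (logx) "x" else "",
       xlab = x$parameter, ylab = "profile log-likelihood", ...)
  graphics::abline(h = x$optimum_logLik - x$threshold, lty = 2)
  graphics::abline(v = x$mle, col = "grey60")
  invisible(x)
}
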