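# Precomputed evaluation plan: maps a named parameter vector (linear scale)
# to model predictions for every row of the dataset, without any name
# lookups in the hot path.
rtf_model_plan <- function(data, spec, t_range = NULL) {
  if (!inherits(data, "rtf_data")) data <- as_timecourse(data)
  stopifnot(inherits(spec, "rtf_spec"))
  multi <- length(spec$conditions) > 1
  if (multi) {
    unknown <- setdiff(unique(data$condition), spec$conditions)
    if (length(unknown))
      stop("data contain condition(s) absent from the spec: ",
           paste(unknown, collapse = ", "))
    conds <- spec$conditions
  } else {
    conds <- unique(data$condition)
  }
  if (is.null(t_range)) t_range <- time_range(data)
  par_names <- spec_param_names(spec)
  np <- length(par_names)
  idx <- function(nm) {
    i <- match(nm, par_names)
    if (is.na(i)) stop("internal: unknown parameter ", nm)
    i
  }

  # per dynamic parameter: how to fill its (M, K, h) triplet from theta
  # kind 0 = fixed to zero, 1 = scalar (constant M), 2 = Hill, 3 = tie
  removed <- spec$fixed_to_zero
  if ("B" %in% removed) removed <- union(removed, c("beta", "gamma"))
  kind <- integer(6); iM <- iK <- ih <- rep(NA_integer_, 6)
  tie_src <- rep(NA_integer_, 6)
  for (j in seq_along(.RTF_DYNAMIC)) {
    p <- .RTF_DYNAMIC[j]
    if (p %in% removed) {
      kind[j] <- 0L
    } else if (!is.null(spec$ties) && p %in% names(spec$ties)) {
      kind[j] <- 3L
      tie_src[j] <- match(spec$ties[[p]], .RTF_DYNAMIC)
    } else if (p %in% spec$dose_dependent) {
      kind[j] <- 2L
      iM[j] <- idx(paste0("M_", p)); iK[j] <- idx(paste0("K_", p))
      ih[j] <- idx(paste0("h_", p))
    } else {
      kind[j] <- 1L
      iM[j] <- idx(p)
    }
  }
  ib <- idx("b"); isigma <- idx("sigma")

  # fold-change instructions per non-reference condition:
  # (dynamic row j, field 1=M/2=K/3=h, theta index of the delta)
  extra <- setdiff(conds, conds[1])
  fc_by_cond <- lapply(conds, function(cond) {
    if (!multi || cond == conds[1] || length(spec$condition_dependent) == 0)
      return(NULL)
    suffix <- if (length(extra) > 1) paste0("_", cond) else ""
    do.call(rbind, lapply(spec$condition_dependent, function(s) {
      loc <- .fc_target(s)
      c(j = match(loc$param, .RTF_DYNAMIC),
        field = match(loc$field, c("M", "K", "h")),
        di = idx(paste0("delta_", s, suffix)))
    }))
  })
  names(fc_by_cond) <- conds

  # row grouping by (condition, dose)
  cond_of_row <- if (multi) data$condition else rep(conds[1], nrow(data))
  ci_of_row <- match(cond_of_row, conds)
  key <- paste(ci_of_row, data$dose, sep = "\r")
  ukey <- unique(key)
  row_group <- match(key, ukey)
  first_row <- match(ukey, key)
  g_ci <- ci_of_row[first_row]
  g_dose <- data$dose[first_row]
  n_groups <- length(ukey)
  times_all <- data$time
  a_scaled <- times_all * 10 / t_range   # transform numerator, fixed per row
  hill_j <- which(kind == 2L)
  sc_j <- which(kind == 1L)
  tie_j <- which(kind == 3L)
  n_rows <- nrow(data)

  predict_theta <- function(theta) {
    val <- matrix(0, 6, n_groups)
    for (ci in seq_along(conds)) {
      M6 <- numeric(6); K6 <- numeric(6); h6 <- rep(1, 6)
      M6[sc_j] <- theta[iM[sc_j]]
      M6[hill_j] <- theta[iM[hill_j]]
      K6[hill_j] <- theta[iK[hill_j]]
      h6[hill_j] <- theta[ih[hill_j]]
      fc <- fc_by_cond[[ci]]
      if (!is.null(fc)) {
        for (r in seq_len(nrow(fc))) {
          j <- fc[r, 1L]; di <- fc[r, 3L]
          if (fc[r, 2L] == 1L) M6[j] <- M6[j] * theta[di]
          else if (fc[r, 2L] == 2L) K6[j] <- K6[j] * theta[di]
          else h6[j] <- h6[j] * theta[di]
        }
      }
      if (length(tie_j)) {
        M6[tie_j] <- M6[tie_src[tie_j]]
        K6[tie_j] <- K6[tie_src[tie_j]]
        h6[tie_j] <- h6[tie_src[tie_j]]
      }
      gsel <- which(g_ci == ci)
      dg <- g_dose[gsel]
      for (j in 1:6) {
        if (K6[j] == 0) {
          # K = 0: constant, no dose dependency
          val[j, gsel] <- M6[j]
        } else {
          dh <- dg^h6[j]
          fr <- dh / (K6[j]^h6[j] + dh)
          val[j, gsel] <- if (j == 6L) M6[j] * (1 - fr) else M6[j] * fr
        }
      }
    }
    A <- val[1, row_group]; B <- val[2, row_group]
    al <- val[3, row_group]; be <- val[4, row_group]
    ga <- val[5, row_group]; ta <- val[6, row_group]
    # stable form of log10(10^a + 10^tau) - log10(1 + 10^tau)
    m1 <- pmax(a_scaled, ta); m0 <- pmax(0, ta)
    tt <- (m1 + log10(10^(a_scaled - m1) + 10^(ta - m1))) -
      (m0 + log10(10^(-m0) + 10^(ta - m0)))
    A * (1 - exp(-al * tt)) + B * (1 - exp(-be * tt)) * exp(-ga * tt) +
      theta[ib]
  }

  # provenance of each (condition, dynamic parameter) triplet scalar:
  # theta index of the base value and of the multiplying fold-change (0 =
  # none), with ties resolved to their source rows.  Used by the analytic
  # gradient.
  base_M <- matrix(NA_integer_, length(conds), 6)
  base_K <- base_h <- base_M
  del_M <- del_K <- del_h <- matrix(0L, length(conds), 6)
  for (ci in seq_along(conds)) {
    base_M[ci, c(sc_j, hill_j)] <- iM[c(sc_j, hill_j)]
    base_K[ci, hill_j] <- iK[hill_j]
    base_h[ci, hill_j] <- ih[hill_j]
    fc <- fc_by_cond[[ci]]
    if (!is.null(fc)) for (r in seq_len(nrow(fc))) {
      j <- fc[r, 1L]
      if (fc[r, 2L] == 1L) del_M[ci, j] <- fc[r, 3L]
      else if (fc[r, 2L] == 2L) del_K[ci, j] <- fc[r, 3L]
      else del_h[ci, j] <- fc[r, 3L]
    }
    if (length(tie_j)) {
      src <- tie_src[tie_j]
      base_M[ci, tie_j] <- base_M[ci, src]; del_M[ci, tie_j] <- del_M[ci, src]
      base_K[ci, tie_j] <- base_K[ci, src]; del_K[ci, tie_j] <- del_K[ci, src]
      base_h[ci, tie_j] <- base_h[ci, src]; del_h[ci, tie_j] <- del_h[ci, src]
    }
  }
  scalar_at <- function(theta, bi, di, default) {
    v <- if (is.na(bi)) default else theta[bi]
    if (di > 0L) v * theta[di] else v
  }

  # analytic gradient of the negative log-likelihood w.r.t. theta (linear
  # scale); mirrors predict_theta's forward pass
  rows_by_group <- split(seq_len(n_rows), row_group)
  grad_nll_theta <- function(theta, y) {
    sigma <- theta[isigma]
    g <- numeric(np)
    ssr <- 0
    sum_w <- 0
    for (gi in seq_len(n_groups)) {
      ci <- g_ci[gi]
      d <- g_dose[gi]
      rows <- rows_by_group[[gi]]
      a <- a_scaled[rows]
      # triplet values and Hill partials at this dose
      v6 <- numeric(6); F6 <- dFdK6 <- dFdh6 <- numeric(6)
      M6 <- K6 <- h6 <- numeric(6)
      const6 <- logical(6)
      for (j in 1:6) {
        M6[j] <- scalar_at(theta, base_M[ci, j], del_M[ci, j], 0)
        K6[j] <- scalar_at(theta, base_K[ci, j], del_K[ci, j], 0)
        h6[j] <- scalar_at(theta, base_h[ci, j], del_h[ci, j], 1)
        if (K6[j] == 0) {          # constant: no dose dependency
          const6[j] <- TRUE
          v6[j] <- M6[j]
        } else if (d == 0) {
          F6[j] <- 0
          v6[j] <- if (j == 6L) M6[j] else 0
        } else {
          dh <- d^h6[j]; Kh <- K6[j]^h6[j]; S <- Kh + dh
          F6[j] <- dh / S
          dFdK6[j] <- -h6[j] * K6[j]^(h6[j] - 1) * dh / S^2
          dFdh6[j] <- dh * Kh * (log(d) - log(K6[j])) / S^2
          v6[j] <- if (j == 6L) M6[j] * (1 - F6[j]) else M6[j] * F6[j]
        }
      }
      A <- v6[1]; B <- v6[2]; al <- v6[3]; be <- v6[4]; ga <- v6[5]
      ta <- v6[6]
      m1 <- pmax(a, ta); m0 <- max(0, ta)
      tt <- (m1 + log10(10^(a - m1) + 10^(ta - m1))) -
        (m0 + log10(10^(-m0) + 10^(ta - m0)))
      e_a <- exp(-al * tt); e_b <- exp(-be * tt); e_g <- exp(-ga * tt)
      mu <- A * (1 - e_a) + B * (1 - e_b) * e_g + theta[ib]
      # objective plateaus (1e10) where predictions overflow; flat gradient
      if (any(!is.finite(mu))) return(numeric(np))
      r <- y[rows] - mu
      ssr <- ssr + sum(r * r)
      w <- -r / sigma^2            # dNLL / dmu
      sum_w <- sum_w + sum(w)
      # dmu/dv for the six dynamic values
      Gv <- numeric(6)
      Gv[1] <- sum(w * (1 - e_a))
      Gv[3] <- sum(w * A * tt * e_a)
      Gv[2] <- sum(w * (1 - e_b) * e_g)
      Gv[4] <- sum(w * B * tt * e_b * e_g)
      Gv[5] <- sum(w * (-B * tt * (1 - e_b) * e_g))
      dmu_dtp <- A * al * e_a + B * (be * e_b - ga * (1 - e_b)) * e_g
      dtp_dtau <- 1 / (10^(a - ta) + 1) - 1 / (10^(-ta) + 1)
      Gv[6] <- sum(w * dmu_dtp * dtp_dtau)
      # chain into the triplet scalars through their provenance
      for (j in 1:6) {
        if (Gv[j] == 0) next
        if (const6[j]) {
          dvdM <- 1; dvdK <- 0; dvdh <- 0
        } else if (j == 6L) {
          dvdM <- 1 - F6[j]
          dvdK <- -M6[j] * dFdK6[j]; dvdh <- -M6[j] * dFdh6[j]
        } else {
          dvdM <- F6[j]
          dvdK <- M6[j] * dFdK6[j]; dvdh <- M6[j] * dFdh6[j]
        }
        acc <- function(bi, di, contrib) {
          if (contrib == 0 || is.na(bi)) return()
          delta_val <- if (di > 0L) theta[di] else 1
          g[bi] <<- g[bi] + contrib * delta_val
          if (di > 0L) g[di] <<- g[di] + contrib * theta[bi]
        }
        acc(base_M[ci, j], del_M[ci, j], Gv[j] * dvdM)
        acc(base_K[ci, j], del_K[ci, j], Gv[j] * dvdK)
        acc(base_h[ci, j], del_h[ci, j], Gv[j] * dvdh)
      }
    }
    g[ib] <- g[ib] + sum_w
    g[isigma] <- g[isigma] + length(y) / sigma - ssr / sigma^3
    g
  }

  list(data = data, spec = spec, conds = conds, t_range = t_range,
       par_names = par_names, n_par = np, isigma = isigma,
       predict = predict_theta, grad_nll = grad_nll_theta)
}

# order/complete a user-supplied theta against the plan
plan_theta <- function(plan, theta) {
  if (is.list(theta)) theta <- unlist(theta)
  missing_par <- setdiff(plan$par_names, names(theta))
  if (length(missing_par))
    stop("missing parameter(s): ", paste(missing_par, collapse = ", "))
  unname(theta[plan$par_names])
}

#' Gaussian log-likelihood of a parameter vector
#'
#' Sum over all measurements (every dose, condition and replicate is an
#' independent observation) of the normal log-density of the residual
#' against the condition- and dose-resolved RTF prediction, with the single
#' shared error SD `sigma` taken from `theta`.
#'
#' @param theta named numeric vector (linear scale) with one entry per free
#'   scalar of the spec (see [rtf_bounds()] for the naming).
#' @param data a time-course data frame.
#' @param spec an [rtf_spec()].
#' @return the log-likelihood (scalar).
#' @export
rtf_loglik <- function(theta, data, spec) {
  plan <- rtf_model_plan(data, spec)
  th <- plan_theta(plan, theta)
  sigma <- th[plan$isigma]
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be > 0")
  mu <- plan$predict(th)
  sum(stats::dnorm(plan$data$value, mu, sigma, log = TRUE))
}

#' Chi-square of a parameter vector at a fixed error SD
#'
#' \eqn{\sum_i (y_i - R_i)^2 / \sigma^2} with an externally fixed
#' \eqn{\sigma}, as used to compare a joint dose-dependent fit with
#' independent single-dose fits on a common scale.
#'
#' @inheritParams rtf_loglik
#' @param sigma_fixed fixed error SD, > 0.
#' @return the chi-square statistic (scalar).
#' @export
rtf_chisq <- function(theta, data, spec, sigma_fixed) {
  if (!is.finite(sigma_fixed) || sigma_fixed <= 0)
    stop("'sigma_fixed' must be > 0")
  plan <- rtf_model_plan(data, spec)
  th <- plan_theta(plan, theta)
  mu <- plan$predict(th)
  sum((plan$data$value - mu)^2) / sigma_fixed^2
}

#' Fit the RTF model by multi-start maximum likelihood
#'
#' Maximizes the Gaussian log-likelihood of the (condition- and
#' dose-resolved) RTF over the box-constrained parameter space by running a
#' bounded quasi-Newton optimizer ([stats::nlminb()]) from multiple start
#' points: the default initial guess plus Latin-hypercube draws (see
#' [rtf_starts()]).  Strictly positive parameters are optimized on the
#' log10 scale.  The best optimum over all starts is returned, together
#' with the sorted final objectives of every start for the waterfall
#' convergence diagnostic; the fit is flagged as reliably converged when at
#' least two starts reach the best log-likelihood within 1e-3.
#'
#' @param data a time-course data frame (see [as_timecourse()]).
#' @param spec an [rtf_spec()] describing the model structure.
#' @param space parameter space; defaults to [rtf_bounds()] on the data.
#' @param n_starts number of optimization starts (default 50).
#' @param seed optional integer seed for the start sampling.
#' @param starts optional matrix of start vectors on the optimization scale
#'   (as produced by [rtf_starts()]); overrides `n_starts`/`seed`.
#' @param control passed to [stats::nlminb()]; sensible tight defaults are
#'   merged in.
#' @return an object of class `"rtf_fit"` with methods [print()],
#'   [summary()], [coef()], [logLik()], [predict()], [residuals()],
#'   [simulate()], [plot()], [profile()] and [confint()].
#' @examples
#' d <- simulate_inflammasome(seed = 1, knockout = FALSE)
#' spec <- rtf_spec(dose_dependent = c("A", "alpha", "tau"),
#'                  fixed_to_zero = "B")
#' fit <- rtf(d, spec, n_starts = 5, seed = 1)
#' coef(fit)
#' @export
rtf <- function(data, spec, space = NULL, n_starts = 50, seed = NULL,
                starts = NULL, control = list()) {
  cl <- match.call()
  data <- as_timecourse(data)
  if (is.null(space)) space <- rtf_bounds(data, spec)
  plan <- rtf_model_plan(data, spec)
  if (!identical(sort(space$name), sort(plan$par_names)))
    stop("parameter space does not match the model spec")
  ord <- match(plan$par_names, space$name)
  space_ord <- space[ord, , drop = FALSE]
  free <- which(!space_ord$fixed)
  theta_full <- space_ord$init
  scales <- space_ord$scale
  lo <- to_scale(space_ord$lower, scales)[free]
  hi <- to_scale(space_ord$upper, scales)[free]

  y <- plan$data$value
  isig <- plan$isigma
  nll <- function(x) {
    th <- theta_full
    th[free] <- from_scale(x, scales[free])
    mu <- plan$predict(th)
    if (any(!is.finite(mu))) return(1e10)
    ll <- sum(stats::dnorm(y, mu, th[isig], log = TRUE))
    if (!is.finite(ll)) 1e10 else -ll
  }
  ln10 <- log(10)
  log_free <- scales[free] == "log10"
  nll_grad <- function(x) {
    th <- theta_full
    th[free] <- from_scale(x, scales[free])
    g <- plan$grad_nll(th, y)[free]
    g[log_free] <- g[log_free] * th[free][log_free] * ln10
    if (any(!is.finite(g))) g[] <- 0
    g
  }

  if (is.null(starts)) starts <- rtf_starts(space, n_starts, seed)
  free_names <- space_ord$name[free]
  if (length(free) > 0) {
    if (!identical(sort(colnames(starts)), sort(free_names)))
      stop("start matrix columns do not match the free parameters")
    starts <- starts[, free_names, drop = FALSE]
  }

  ctrl <- utils::modifyList(
    list(eval.max = 2000, iter.max = 500, rel.tol = 1e-10, x.tol = 1.5e-8),
    control)
  res <- vector("list", nrow(starts))
  if (length(free) == 0) {
    # fully constrained model: nothing to optimize, evaluate at the inits
    res <- list(list(objective = nll(numeric(0)), convergence = 0L,
                     par = numeric(0)))
    starts <- starts[1, , drop = FALSE]
  } else for (i in seq_len(nrow(starts))) {
    x0 <- pmin(pmax(starts[i, ], lo), hi)
    res[[i]] <- tryCatch(
      stats::nlminb(x0, nll, gradient = nll_grad, lower = lo, upper = hi,
                    control = ctrl),
      error = function(e) list(objective = Inf, convergence = 1L,
                               message = conditionMessage(e), par = x0))
  }
  objs <- vapply(res, function(r) r$objective, numeric(1))
  if (all(!is.finite(objs)))
    stop("optimization failed for every start; diagnostics: ",
         paste(unique(vapply(res, function(r)
       as.character(r$message %||% "non-finite objective"), character(1))),
       collapse = "; "))
  best <- which.min(objs)
  x_hat <- pmin(pmax(res[[best]]$par, lo), hi)
  theta_hat <- theta_full
  theta_hat[free] <- from_scale(x_hat, scales[free])
  names(theta_hat) <- plan$par_names
  mu_hat <- plan$predict(theta_hat)

  structure(list(
    coefficients = theta_hat[free_names],
    theta = theta_hat,
    logLik = -objs[best],
    fitted.values = mu_hat,
    residuals = y - mu_hat,
    starts = data.frame(start = order(objs),
                        objective = sort(objs)),
    converged_repeatedly = sum(objs <= objs[best] + 1e-3) >= 2,
    convergence = res[[best]]$convergence,
    spec = spec, space = space_ord, data = data,
    t_range = plan$t_range,
    n_starts = nrow(starts), seed = seed,
    n_free = length(free), nobs = length(y),
    call = cl), class = "rtf_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Waterfall diagnostic of a multi-start fit
#'
#' The final objective values (negative log-likelihoods) of all
#' optimization starts, sorted ascending.  A flat initial plateau indicates
#' that the best optimum was found repeatedly and can be trusted as the
#' global one.
#'
#' @param fit an [rtf()] fit.
#' @return data frame with columns `rank`, `start` (index of the start) and
#'   `objective`, sorted non-decreasing.
#' @export
waterfall <- function(fit) {
  stopifnot(inherits(fit, "rtf_fit"))
  data.frame(rank = seq_len(nrow(fit$starts)),
             start = fit$starts$start,
             objective = fit$starts$objective)
}

#' @export
print.rtf_fit <- function(x, digits = 4, ...) {
  cat("Dose-dependent RTF fit\n")
  cat("  log-likelihood:", format(x$logLik, digits = 7),
      " (", x$n_free, "free parameters,", x$nobs, "observations )\n")
  cat("  best optimum found",
      if (x$converged_repeatedly) "repeatedly" else "only once",
      "over", x$n_starts, "starts\n")
  print(round(x$coefficients, digits), ...)
  invisible(x)
}

#' @export
summary.rtf_fit <- function(object, ...) {
  n_best <- sum(object$starts$objective <=
                  min(object$starts$objective) + 1e-3)
  structure(list(fit = object,
                 n_best = n_best,
                 sigma_hat = unname(object$theta["sigma"]),
                 rss = sum(object$residuals^2)),
            class = "summary.rtf_fit")
}

#' @export
print.summary.rtf_fit <- function(x, ...) {
  print(x$fit)
  cat("  residual SD (fitted sigma):", format(x$sigma_hat, digits = 4), "\n")
  cat("  residual sum of squares:   ", format(x$rss, digits = 4), "\n")
  cat("  starts reaching the optimum (within 1e-3):", x$n_best, "\n")
  invisible(x)
}

#' @export
coef.rtf_fit <- function(object, ...) object$coefficients

#' @export
logLik.rtf_fit <- function(object, ...) {
  structure(object$logLik, df = object$n_free, nobs = object$nobs,
            class = "logLik")
}

#' @export
residuals.rtf_fit <- function(object, ...) object$residuals

#' @export
fitted.rtf_fit <- function(object, ...) object$fitted.values

#' Model predictions on new time/dose/condition points
#'
#' @param object an [rtf()] fit.
#' @param newdata data frame with columns `time`, `dose` and (for
#'   multi-condition fits) `condition`; defaults to the training data.  The
#'   training dataset's time range is reused, so predictions are valid for
#'   interpolation and moderate extrapolation on the same time axis.
#' @param ... unused.
#' @return numeric vector of expected responses.
#' @export
predict.rtf_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted.values)
  nd <- as.data.frame(newdata)
  if (!"condition" %in% names(nd))
    nd$condition <- object$spec$reference_condition
  missing_cols <- setdiff(c("time", "dose"), names(nd))
  if (length(missing_cols))
    stop("newdata lacks column(s): ", paste(missing_cols, collapse = ", "))
  nd$replicate <- 1L
  nd$value <- 0
  nd <- nd[, c("time", "dose", "condition", "replicate", "value")]
  class(nd) <- c("rtf_data", "data.frame")
  # evaluate on the new grid, keeping the training time range so that the
  # transformed time axis matches the fit
  plan <- rtf_model_plan(nd, object$spec, t_range = object$t_range)
  plan$predict(plan_theta(plan, object$theta))
}

#' Parametric simulation from a fitted model
#'
#' Draws new datasets from the fitted RTF surface plus Gaussian noise with
#' the fitted `sigma`.
#'
#' @param object an [rtf()] fit.
#' @param nsim number of simulated datasets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return a data frame with one column `sim_1`, ..., `sim_nsim` per
#'   simulation, rows aligned with the training data.
#' @export
simulate.rtf_fit <- function(object, nsim = 1, seed = NULL, ...) {
  mu <- object$fitted.values
  sigma <- object$theta[["sigma"]]
  sims <- with_seed(seed, replicate(nsim, mu + stats::rnorm(length(mu), 0, sigma)))
  out <- as.data.frame(sims)
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' Plot a fitted RTF model or its waterfall diagnostic
#'
#' @param x an [rtf()] fit.
#' @param which `"fit"` (data and fitted curves, one panel per condition,
#'   one colour per dose) or `"waterfall"` (sorted final objectives of the
#'   multi-start optimization).
#' @param n_grid number of time points per fitted curve.
#' @param ... passed to the underlying plotting functions.
#' @return `x`, invisibly.
#' @export
plot.rtf_fit <- function(x, which = c("fit", "waterfall"), n_grid = 101, ...) {
  which <- match.arg(which)
  if (which == "waterfall") {
    wf <- waterfall(x)
    plot(wf$rank, wf$objective, type = "b", pch = 19,
         xlab = "sorted start index", ylab = "negative log-likelihood",
         main = "Waterfall diagnostic", ...)
    return(invisible(x))
  }
  d <- x$data
  conds <- unique(d$condition)
  doses <- sort(unique(d$dose))
  cols <- grDevices::hcl.colors(max(length(doses), 2), "viridis")
  old <- graphics::par(mfrow = c(1, length(conds)))
  on.exit(graphics::par(old))
  tgrid <- seq(min(d$time), max(d$time), length.out = n_grid)
  for (cond in conds) {
    sub <- d[d$condition == cond, ]
    plot(sub$time, sub$value, pch = 19, cex = 0.6,
         col = cols[match(sub$dose, doses)],
         xlab = "time", ylab = "response", main = cond, ...)
    for (k in seq_along(doses)) {
      nd <- data.frame(time = tgrid, dose = doses[k], condition = cond)
      graphics::lines(tgrid, predict(x, nd), col = cols[k])
    }
  }
  invisible(x)
}
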