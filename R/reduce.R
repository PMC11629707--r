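# removable terms of a spec: dose dependencies (K -> 0, h dropped) and
# condition dependencies (delta -> 1); terms in `protect` are never offered
reduction_candidates <- function(spec, protect = character()) {
  cands <- list()
  for (p in setdiff(spec$dose_dependent, protect))
    cands[[length(cands) + 1L]] <- list(type = "dose", param = p,
                                        label = paste0("dose(", p, ")"))
  for (s in setdiff(spec$condition_dependent, protect))
    cands[[length(cands) + 1L]] <- list(type = "condition", param = s,
                                        label = paste0("condition(", s, ")"))
  cands
}

# carry estimates of the current model over to a reduced spec's space,
# clamped into bounds; used to warm-start tentative refits
map_estimates <- function(est, space) {
  warm <- space$init
  for (i in seq_len(nrow(space))) {
    nm <- space$name[i]
    v <- if (nm %in% names(est)) est[[nm]]
         else if (paste0("M_", nm) %in% names(est)) est[[paste0("M_", nm)]]
         else next
    warm[i] <- min(max(v, space$lower[i]), space$upper[i])
  }
  stats::setNames(to_scale(warm, space$scale), space$name)[!space$fixed]
}

#' Backward elimination of dose and condition dependencies
#'
#' Greedy model reduction: at each round every removable term — a dose
#' dependency (pinning its `K` to 0, which also removes the then-irrelevant
#' Hill coefficient `h`) or a condition dependency (fixing its fold-change
#' \eqn{\Delta} to 1) — is tentatively removed, the reduced model is
#' refitted (warm-started from the current estimates plus fresh
#' Latin-hypercube starts) and compared to the current model by a
#' likelihood-ratio test.  The term with the largest p-value is removed
#' permanently if that p-value exceeds `alpha`; the procedure stops when
#' every remaining removal would significantly worsen the fit.  The
#' returned trail records every decision so order effects can be audited.
#'
#' @param data a time-course data frame.
#' @param spec the full starting [rtf_spec()].
#' @param alpha significance threshold for refusing a removal (default
#'   0.05).
#' @param n_starts fresh Latin-hypercube starts per tentative refit, in
#'   addition to the warm start (default 10).
#' @param seed optional integer seed (start sampling).
#' @param fit optional already-computed fit of `spec` on `data`; computed
#'   with `n_starts_initial` starts when absent.
#' @param n_starts_initial starts for the initial full fit (default 20).
#' @param protect character vector of terms never offered for removal
#'   (prior knowledge), named as in the trail, e.g. `"A"` for a dose
#'   dependency or `"M_A"` for a condition dependency.
#' @return an object of class `"rtf_reduction"`: `trail` (one row per
#'   tested removal: step, term, LRT statistic, df, p-value,
#'   log-likelihoods before/after, decision), `spec` (final structure),
#'   `fit` (final fit), `alpha`.
#' @export
backward_eliminate <- function(data, spec, alpha = 0.05, n_starts = 10,
                               seed = NULL, fit = NULL,
                               n_starts_initial = 20,
                               protect = character()) {
  data <- as_timecourse(data)
  if (is.null(fit))
    fit <- rtf(data, spec, n_starts = n_starts_initial, seed = seed)
  current <- list(spec = spec, fit = fit)
  trail <- list()
  step <- 0L
  sub_seed <- if (is.null(seed)) NULL else seed

  repeat {
    cands <- reduction_candidates(current$spec, protect)
    if (length(cands) == 0) break
    step <- step + 1L
    tested <- lapply(cands, function(cand) {
      rspec <- tryCatch(
        if (cand$type == "dose")
          eliminate_dose_dependency(current$spec, cand$param)
        else
          eliminate_condition_dependency(current$spec, cand$param),
        error = function(e) NULL)
      if (is.null(rspec)) return(NULL)
      rspace <- rtf_bounds(data, rspec)
      warm <- map_estimates(current$fit$coefficients, rspace)
      if (!is.null(sub_seed))
        sub_seed <<- (sub_seed + 7L) %% .Machine$integer.max
      starts <- rbind(matrix(warm, nrow = 1,
                             dimnames = list(NULL, names(warm))),
                      rtf_starts(rspace, n_starts, sub_seed))
      rfit <- tryCatch(rtf(data, rspec, space = rspace, starts = starts),
                       error = function(e) NULL)
      if (is.null(rfit)) return(NULL)
      df <- current$fit$n_free - rfit$n_free
      test <- suppressWarnings(lrt(rfit, current$fit, df = df))
      list(cand = cand, spec = rspec, fit = rfit, df = df,
           stat = unname(test$statistic), p = test$p.value)
    })
    ok <- !vapply(tested, is.null, logical(1))
    tested <- tested[ok]
    if (length(tested) == 0) break
    ps <- vapply(tested, function(t) t$p, numeric(1))
    best <- tested[[which.max(ps)]]
    removed <- best$p > alpha
    trail[[length(trail) + 1L]] <- data.frame(
      step = step, term = best$cand$label, type = best$cand$type,
      statistic = best$stat, df = best$df, p.value = best$p,
      logLik_before = current$fit$logLik, logLik_after = best$fit$logLik,
      decision = if (removed) "removed" else "kept", stringsAsFactors = FALSE)
    if (!removed) break
    current <- list(spec = best$spec, fit = best$fit)
  }

  structure(list(trail = if (length(trail)) do.call(rbind, trail)
                         else data.frame(),
                 spec = current$spec, fit = current$fit, alpha = alpha),
            class = "rtf_reduction")
}

#' @export
print.rtf_reduction <- function(x, ...) {
  cat("Backward elimination (alpha = ", x$alpha, ")\n", sep = "")
  if (nrow(x$trail) == 0) {
    cat("  no removable terms; model unchanged\n")
  } else {
    print(x$trail, ...)
  }
  cat("Final model: ", x$fit$n_free, " free parameters, log-likelihood ",
      format(x$fit$logLik, digits = 7), "\n", sep = "")
  invisible(x)
}
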