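#' Default parameter bounds and initial guesses
#'
#' Builds the box-constrained parameter space for a model structure on a
#' dataset, one row per free scalar, following the package's default
#' bounds:
#' \itemize{
#'   \item amplitudes `M_A`, `M_B` (or plain `A`, `B`): \eqn{[0, 2(\max y -
#'     \min y)]}, initial guess \eqn{0.1\,lb + 0.9\,ub}; mirrored to
#'     \eqn{[-ub, 0]} for down-regulated amplitudes;
#'   \item rates `M_alpha`, `M_beta`, `M_gamma`: \eqn{[1 / (2 (\max t' -
#'     \min t')),\; 2 / \min_i(t'_{i+1} - t'_i)]} with \eqn{t'} the sorted
#'     distinct measurement times, initial guess the midpoint;
#'   \item time shift `M_tau`: \eqn{[-(\max t' - \min t')/5,\;(\max t' -
#'     \min t')/2]}, initial guess \eqn{-(\max t' - \min t')/10};
#'   \item Hill coefficients `h_*`: \eqn{[1, 10]}; half-maximal doses
#'     `K_*`: \eqn{[\min(dose > 0)/10,\; 10 \max(dose)]} (shared bounds for
#'     all dose-dependent parameters), initial guess the midpoint;
#'   \item offset `b`: \eqn{[\min y, \max y]}; error SD `sigma`:
#'     \eqn{[\min(ub, \max(10^{-10}, (\max y - \min y)/10^4)),\;
#'     \max(10^{-10}, SD(y))]}, initial guesses the midpoints;
#'   \item fold-changes `delta_*`: \eqn{[10^{-2}, 10^{2}]}, initial guess 1
#'     (no condition effect).
#' }
#' When several conditions are present, only the reference-condition data
#' define the `y`-based bounds.  Strictly positive parameters (rates, `K`,
#' `h`, `sigma`, fold-changes) are optimized on the log10 scale; amplitudes,
#' the time shift and the offset (which may be zero or negative) stay
#' linear.
#'
#' @param data a time-course data frame (see [as_timecourse()]).
#' @param spec an [rtf_spec()].
#' @return a data frame of class `"rtf_space"` with columns `name`,
#'   `lower`, `upper`, `init`, `scale` (`"linear"` or `"log10"`) and
#'   `fixed`.
#' @export
rtf_bounds <- function(data, spec) {
  data <- as_timecourse(data)
  stopifnot(inherits(spec, "rtf_spec"))
  missing_conds <- setdiff(spec$conditions, unique(data$condition))
  if (length(spec$conditions) > 1 && length(missing_conds))
    stop("condition(s) not present in data: ",
         paste(missing_conds, collapse = ", "))
  y <- if (length(spec$conditions) > 1)
    data$value[data$condition == spec$reference_condition] else data$value
  tp <- sort(unique(data$time))
  if (length(tp) < 2 || diff(range(tp)) == 0)
    stop("degenerate bounds: all measurement times identical")
  t_span <- max(tp) - min(tp)
  t_gap <- min(diff(tp))
  y_span <- max(y) - min(y)
  if (length(spec$dose_dependent)) {
    pos_doses <- unique(data$dose[data$dose > 0])
    if (length(unique(data$dose)) < 2)
      stop("dose-dependent parameters require at least 2 distinct doses")
    if (length(pos_doses) == 0)
      stop("dose-dependent parameters require positive doses")
    K_lb <- min(pos_doses) / 10
    K_ub <- max(data$dose) * 10
  }

  rows <- list()
  add <- function(name, lower, upper, init, scale) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, lower = lower, upper = upper, init = init,
      scale = scale, fixed = FALSE, stringsAsFactors = FALSE)
  }
  amp_row <- function(name, par) {
    down <- identical(unname(spec$sign[par]), "down")
    if (down) add(name, -2 * y_span, 0, 0.9 * (-2 * y_span), "linear")
    else      add(name, 0, 2 * y_span, 0.9 * (2 * y_span), "linear")
  }
  rate_row <- function(name) {
    lb <- 1 / (2 * t_span); ub <- 2 / t_gap
    add(name, lb, ub, 0.5 * (lb + ub), "log10")
  }
  for (p in spec_active_dynamic(spec)) {
    base <- if (p %in% spec$dose_dependent) paste0("M_", p) else p
    switch(p,
      A = amp_row(base, "A"),
      B = amp_row(base, "B"),
      alpha = rate_row(base),
      beta = rate_row(base),
      gamma = rate_row(base),
      tau = add(base, -t_span / 5, t_span / 2, -t_span / 10, "linear"))
    if (p %in% spec$dose_dependent) {
      add(paste0("K_", p), K_lb, K_ub, 0.5 * (K_lb + K_ub), "log10")
      add(paste0("h_", p), 1, 10, 5.5, "log10")
    }
  }
  add("b", min(y), max(y), 0.5 * (min(y) + max(y)), "linear")
  s_ub <- max(1e-10, stats::sd(y))
  s_lb <- min(s_ub, max(1e-10, y_span / 1e4))
  add("sigma", s_lb, s_ub, 0.5 * (s_lb + s_ub), "log10")
  for (nm in spec_delta_names(spec)) add(nm, 1e-2, 1e2, 1, "log10")

  space <- do.call(rbind, rows)
  bad <- space$init < space$lower | space$init > space$upper
  if (any(bad))
    stop("initial guess outside bounds for: ",
         paste(space$name[bad], collapse = ", "))
  if (any(space$scale == "log10" & space$lower <= 0))
    stop("log10-scaled parameters need strictly positive bounds")
  class(space) <- c("rtf_space", "data.frame")
  space
}

#' Fix parameters at given values
#'
#' Marks parameters as fixed (excluded from optimization and profiling) at
#' the supplied values.
#'
#' @param space an [rtf_bounds()] space.
#' @param values named numeric vector: parameter name -> fixed value
#'   (linear scale).
#' @return the modified space.
#' @export
fix_parameters <- function(space, values) {
  stopifnot(inherits(space, "rtf_space"))
  bad <- setdiff(names(values), space$name)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(values)) {
    i <- match(nm, space$name)
    space$init[i] <- values[[nm]]
    space$lower[i] <- min(space$lower[i], values[[nm]])
    space$upper[i] <- max(space$upper[i], values[[nm]])
    space$fixed[i] <- TRUE
  }
  space
}

# linear -> optimizer scale and back
to_scale <- function(x, scale) {
  i <- scale == "log10"
  x[i] <- log10(x[i])
  x
}
from_scale <- function(x, scale) {
  i <- scale == "log10"
  x[i] <- 10^x[i]
  x
}

#' Multi-start initial values
#'
#' The first start is the default initial guess of the space; the remaining
#' `n_starts - 1` are a Latin-hypercube sample over the free parameters'
#' boxes, drawn on each parameter's optimization scale (log10 for strictly
#' positive parameters), so starts are spread over orders of magnitude
#' where appropriate.
#'
#' @param space an [rtf_bounds()] space.
#' @param n_starts total number of starts, >= 1.
#' @param seed optional integer seed; same seed, same draws.
#' @return a matrix (`n_starts` rows) of start values on the optimization
#'   scale, columns named by the free parameters.
#' @export
rtf_starts <- function(space, n_starts, seed = NULL) {
  stopifnot(inherits(space, "rtf_space"), n_starts >= 1)
  free <- space[!space$fixed, , drop = FALSE]
  if (nrow(free) == 0)
    return(matrix(numeric(0), nrow = n_starts, ncol = 0))
  lo <- to_scale(free$lower, free$scale)
  hi <- to_scale(free$upper, free$scale)
  starts <- matrix(to_scale(free$init, free$scale), nrow = 1)
  if (n_starts > 1) {
    u <- with_seed(seed, lhs::randomLHS(n_starts - 1L, nrow(free)))
    starts <- rbind(starts, sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+"))
  }
  colnames(starts) <- free$name
  starts
}

#' @export
print.rtf_space <- function(x, ...) {
  cat("RTF parameter space (", sum(!x$fixed), " free, ",
      sum(x$fixed), " fixed):\n", sep = "")
  NextMethod()
}
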