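.RTF_DYNAMIC <- c("A", "B", "alpha", "beta", "gamma", "tau")

#' Model structure specification
#'
#' Declares which RTF parameters exist, which are dose-dependent (carry a
#' Hill triplet), which are fixed to zero, which are tied to another
#' parameter, and which scalars differ between biological conditions via
#' fold-changes.
#'
#' Fixing `B` to zero removes the whole transient component, i.e. `beta`
#' and `gamma` disappear as well.  A tied parameter (default: `beta` and
#' `gamma` both tied to `alpha`, since the sustained and transient parts of
#' a response are usually triggered together) contributes no free scalars
#' and mirrors its target completely, including any dose dependency; ties
#' whose source has been removed are dropped silently, while a tie whose
#' target is removed is an error.
#'
#' @param dose_dependent character vector, subset of
#'   `c("A","B","alpha","beta","gamma","tau")`: parameters replaced by Hill
#'   dose dependencies (each contributes free scalars `M_*`, `K_*`, `h_*`).
#' @param fixed_to_zero character vector of parameters pinned to 0
#'   (typically `"B"` for sustained-only responses).
#' @param ties named character vector: `c(gamma = "alpha")` ties `gamma` to
#'   `alpha`.  Default ties both transient rates to `alpha`; use
#'   `ties = NULL` for the fully free model.
#' @param sign named character vector with entries `"up"` or `"down"` for
#'   amplitudes `A` and/or `B`; `"down"` flips the sign of the default
#'   amplitude bounds to describe down-regulation.
#' @param conditions character vector of condition labels; the first is the
#'   reference condition.
#' @param condition_dependent character vector of free scalar names
#'   (e.g. `"M_A"`, `"K_alpha"`, `"h_tau"`, or a bare name such as `"tau"`
#'   for a non-dose-dependent parameter) that carry a fold-change
#'   \eqn{\Delta} in every non-reference condition.
#' @return an object of class `"rtf_spec"`.
#' @examples
#' # sustained-only model with Hill dose dependencies on A, alpha, tau:
#' rtf_spec(dose_dependent = c("A", "alpha", "tau"), fixed_to_zero = "B")
#' @export
rtf_spec <- function(dose_dependent = character(),
                     fixed_to_zero = character(),
                     ties = c(beta = "alpha", gamma = "alpha"),
                     sign = c(A = "up", B = "up"),
                     conditions = "all",
                     condition_dependent = character()) {
  bad <- setdiff(c(dose_dependent, fixed_to_zero), .RTF_DYNAMIC)
  if (length(bad))
    stop("unknown dynamic parameter(s): ", paste(bad, collapse = ", "))
  removed <- fixed_to_zero
  if ("B" %in% fixed_to_zero) removed <- union(removed, c("beta", "gamma"))
  if (!is.null(ties)) {
    if (is.null(names(ties)) || any(!nzchar(names(ties))))
      stop("'ties' must be a named character vector (tied = target)")
    keep <- !(names(ties) %in% removed)
    if (any(ties[keep] %in% removed))
      stop("cannot tie a parameter to one that is fixed to zero: ",
           paste(ties[keep][ties[keep] %in% removed], collapse = ", "))
    ties <- ties[keep]
    if (any(names(ties) == ties)) stop("a parameter cannot be tied to itself")
    if (length(ties) == 0) ties <- NULL
  }
  tied <- names(ties)
  dose_dependent <- setdiff(dose_dependent, union(removed, tied))
  if (anyDuplicated(conditions)) stop("duplicate condition labels")
  if (length(conditions) < 1) stop("at least one condition label required")
  if (length(condition_dependent) && length(conditions) < 2)
    stop("condition-dependent parameters require at least two conditions")
  if (!all(sign %in% c("up", "down")))
    stop("'sign' entries must be \"up\" or \"down\"")
  spec <- structure(
    list(dose_dependent = dose_dependent,
         fixed_to_zero = fixed_to_zero,
         ties = ties,
         sign = sign,
         conditions = as.character(conditions),
         reference_condition = as.character(conditions)[1],
         condition_dependent = condition_dependent),
    class = "rtf_spec")
  bad_cd <- setdiff(condition_dependent, spec_scalar_names(spec))
  if (length(bad_cd))
    stop("condition_dependent entries are not free scalars of this model: ",
         paste(bad_cd, collapse = ", "))
  spec
}

# dynamic parameters that carry free scalars (not removed, not tied)
spec_active_dynamic <- function(spec) {
  removed <- spec$fixed_to_zero
  if ("B" %in% removed) removed <- union(removed, c("beta", "gamma"))
  setdiff(.RTF_DYNAMIC, union(removed, names(spec$ties)))
}

# free scalar names of the reference condition (no deltas, no b/sigma)
spec_scalar_names <- function(spec) {
  unlist(lapply(spec_active_dynamic(spec), function(p) {
    if (p %in% spec$dose_dependent) paste0(c("M_", "K_", "h_"), p) else p
  }), use.names = FALSE)
}

# fold-change parameter names, one per (non-reference condition x scalar)
spec_delta_names <- function(spec) {
  extra <- setdiff(spec$conditions, spec$reference_condition)
  if (length(extra) == 0 || length(spec$condition_dependent) == 0)
    return(character())
  unlist(lapply(extra, function(cond) {
    suffix <- if (length(extra) > 1) paste0("_", cond) else ""
    paste0("delta_", spec$condition_dependent, suffix)
  }), use.names = FALSE)
}

# all free parameter names, in canonical order
spec_param_names <- function(spec) {
  c(spec_scalar_names(spec), "b", "sigma", spec_delta_names(spec))
}

#' Count free parameters of a model structure
#'
#' Each dose-dependent dynamic parameter contributes the three Hill scalars
#' `M`, `K`, `h`; each plain (non-dose-dependent) one contributes a single
#' value; the offset `b` and error SD `sigma` always count; every
#' non-reference condition adds one fold-change \eqn{\Delta} per
#' condition-dependent scalar.  Tied and fixed-to-zero parameters
#' contribute nothing.
#'
#' @param spec an [rtf_spec()].
#' @param n_doses optional: when fitting each of `n_doses` doses with an
#'   independent single-dose model, the per-dose count is multiplied by
#'   `n_doses` (only meaningful for a spec without dose dependencies).
#' @return integer count of free scalar parameters.
#' @examples
#' full <- c("A", "B", "alpha", "beta", "gamma", "tau")
#' n_free_parameters(rtf_spec(dose_dependent = full, ties = NULL))         # 20
#' n_free_parameters(rtf_spec(dose_dependent = c("A", "alpha", "tau"),
#'                            fixed_to_zero = "B"))                        # 11
#' @export
n_free_parameters <- function(spec, n_doses = NULL) {
  stopifnot(inherits(spec, "rtf_spec"))
  n <- length(spec_param_names(spec))
  if (!is.null(n_doses)) {
    if (length(spec$dose_dependent))
      stop("per-dose counting requires a spec without dose dependencies")
    n <- n * as.integer(n_doses)
  }
  as.integer(n)
}

#' Remove the dose dependency of a parameter
#'
#' Pins the parameter's half-maximal dose `K` to zero, which makes its Hill
#' curve constant; the Hill coefficient `h` then has no influence and is
#' removed as well, so the free-parameter count drops by two.  A
#' fold-change previously attached to `M_<param>` is re-attached to the now
#' plain parameter; fold-changes on its `K` or `h` are dropped.
#'
#' @param spec an [rtf_spec()].
#' @param param name of a currently dose-dependent parameter.
#' @return the reduced [rtf_spec()].
#' @export
eliminate_dose_dependency <- function(spec, param) {
  stopifnot(inherits(spec, "rtf_spec"))
  if (!param %in% spec$dose_dependent)
    stop("'", param, "' is not dose-dependent in this spec")
  cd <- spec$condition_dependent
  cd <- setdiff(cd, paste0(c("K_", "h_"), param))
  cd[cd == paste0("M_", param)] <- param
  rtf_spec(dose_dependent = setdiff(spec$dose_dependent, param),
           fixed_to_zero = spec$fixed_to_zero,
           ties = spec$ties, sign = spec$sign,
           conditions = spec$conditions,
           condition_dependent = cd)
}

#' Remove the condition dependency of a scalar
#'
#' Fixes the scalar's fold-change \eqn{\Delta} to 1 so the scalar is shared
#' across all conditions; the free-parameter count drops by the number of
#' non-reference conditions.
#'
#' @param spec an [rtf_spec()].
#' @param param name of a scalar currently in `condition_dependent`.
#' @return the reduced [rtf_spec()].
#' @export
eliminate_condition_dependency <- function(spec, param) {
  stopifnot(inherits(spec, "rtf_spec"))
  if (!param %in% spec$condition_dependent)
    stop("'", param, "' is not condition-dependent in this spec")
  rtf_spec(dose_dependent = spec$dose_dependent,
           fixed_to_zero = spec$fixed_to_zero,
           ties = spec$ties, sign = spec$sign,
           conditions = spec$conditions,
           condition_dependent = setdiff(spec$condition_dependent, param))
}

#' @export
print.rtf_spec <- function(x, ...) {
  cat("RTF model specification\n")
  cat("  dynamic parameters:  ",
      paste(spec_active_dynamic(x), collapse = ", "), "\n")
  cat("  dose-dependent:      ",
      if (length(x$dose_dependent)) paste(x$dose_dependent, collapse = ", ")
      else "(none)", "\n")
  if (length(x$fixed_to_zero))
    cat("  fixed to zero:       ", paste(x$fixed_to_zero, collapse = ", "), "\n")
  if (length(x$ties))
    cat("  ties:                ",
        paste(names(x$ties), "=", x$ties, collapse = ", "), "\n")
  cat("  conditions:          ", paste(x$conditions, collapse = ", "),
      if (length(x$conditions) > 1)
        paste0(" (reference: ", x$reference_condition, ")") else "", "\n", sep = "")
  if (length(x$condition_dependent))
    cat("  condition-dependent: ",
        paste(x$condition_dependent, collapse = ", "), "\n")
  cat("  free parameters:     ", n_free_parameters(x), "\n")
  invisible(x)
}
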