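#' Validate a long-format time-course table
#'
#' Checks that a data frame holds one measurement per row in the tidy
#' schema `time, dose, condition, replicate, value` (with `replicate`
#' defaulting to 1 when absent), that times and doses are numeric, doses
#' non-negative, and that the design spans a positive time range with at
#' least three distinct time points.
#'
#' @param data a data frame.
#' @return the validated data frame with class `"rtf_data"`, columns in
#'   canonical order and `condition` as character.
#' @export
as_timecourse <- function(data) {
  if (!is.data.frame(data)) stop("'data' must be a data frame")
  required <- c("time", "dose", "condition", "value")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  if (!"replicate" %in% names(data)) data$replicate <- 1L
  data <- as.data.frame(data)[, c("time", "dose", "condition", "replicate", "value")]
  if (nrow(data) == 0) stop("time-course table has no rows")
  for (col in c("time", "dose", "value")) {
    if (!is.numeric(data[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(data[[col]])))))
      stop("column '", col, "' is not numeric",
           if (length(bad)) paste0(" (offending row(s): ",
                                   paste(utils::head(bad, 5), collapse = ", "), ")"))
    }
  }
  if (anyNA(data$time) || anyNA(data$dose) || anyNA(data$value))
    stop("missing values in time/dose/value are not allowed")
  for (col in c("time", "dose", "value")) data[[col]] <- as.double(data[[col]])
  neg <- which(data$dose < 0)
  if (length(neg))
    stop("negative dose in row(s): ", paste(utils::head(neg, 5), collapse = ", "))
  data$condition <- as.character(data$condition)
  if (length(unique(data$time)) < 3)
    stop("at least 3 distinct time points are required")
  if (diff(range(data$time)) <= 0) stop("time range must be positive")
  class(data) <- c("rtf_data", "data.frame")
  data
}

#' Dataset time range
#'
#' `max(time) - min(time)` over all doses, conditions and replicates; the
#' one scale shared by every curve of a dataset so that all conditions live
#' on a common transformed time axis.
#'
#' @param data a time-course data frame.
#' @return positive scalar.
#' @export
time_range <- function(data) {
  diff(range(data$time))
}

#' Read a tidy time-course CSV
#'
#' Expects a header with columns `time`, `dose`, `condition`, `value` and
#' optionally `replicate` (defaulting to 1), UTF-8, `"."` as decimal
#' separator.  Non-numeric or negative-dose rows are rejected with
#' row-numbered messages.
#'
#' @param path path to a CSV file.
#' @return an [as_timecourse()] validated data frame.
#' @export
read_timecourse <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stop("empty time-course file: ", path)
  as_timecourse(raw)
}

#' Write a tidy time-course CSV
#'
#' Numeric columns are written as decimal text with 17 significant digits,
#' so a write/read roundtrip reproduces every double bit-exactly.
#'
#' @param data a time-course data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(data, path) {
  data <- as_timecourse(data)
  out <- data.frame(
    time = format(data$time, digits = 17, trim = TRUE, scientific = FALSE),
    dose = format(data$dose, digits = 17, trim = TRUE, scientific = FALSE),
    condition = data$condition,
    replicate = data$replicate,
    value = format(data$value, digits = 17, trim = TRUE, scientific = FALSE),
    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Simulate a time- and dose-dependent signalling dataset
#'
#' Draws measurements from the dose-dependent RTF plus independent additive
#' Gaussian noise with a single SD `sigma` (the generative model the
#' fitting machinery assumes).  Multiple biological conditions are
#' expressed as fold-changes relative to the first (reference) parameter
#' set.
#'
#' @param pars an [rtf_dose_params()] object for the reference condition,
#'   or a named list of such objects (one per condition; the first is the
#'   reference).
#' @param doses numeric vector of doses (the dose ladder).
#' @param times numeric vector of measurement times.
#' @param n_replicates number of independent replicates per (time, dose,
#'   condition) cell.
#' @param sigma noise SD, >= 0; 0 returns noise-free model values.
#' @param fold_changes optional named list: one fold-change set (see
#'   [rtf_apply_fold_changes()]) per non-reference condition, applied to
#'   `pars` when `pars` is a single parameter set.
#' @param reference name of the reference condition.
#' @param seed optional integer seed; the same seed reproduces the dataset
#'   exactly.  The caller's RNG state is left untouched.
#' @return an [as_timecourse()] data frame with attribute `"truth"` holding
#'   the generating parameter sets by condition, plus `"sigma"` and
#'   `"seed"`.
#' @examples
#' dp <- rtf_dose_params(A = rtf_hill_triplet(1, 4, 2), B = 0, alpha = 0.8,
#'                       beta = 0.8, gamma = 0.8,
#'                       tau = rtf_hill_triplet(2, 5, 2), b = 0.05,
#'                       sigma = 0.02)
#' d <- simulate_timecourse(dp, doses = 1:5, times = 0:6, n_replicates = 2,
#'                          sigma = 0.02, seed = 1)
#' @export
simulate_timecourse <- function(pars, doses, times, n_replicates = 1,
                                sigma = 0, fold_changes = NULL,
                                reference = "reference", seed = NULL) {
  if (length(doses) == 0 || length(times) == 0) stop("empty dose or time grid")
  if (sigma < 0) stop("'sigma' must be >= 0")
  if (inherits(pars, "rtf_dose_params")) {
    by_cond <- c(stats::setNames(list(pars), reference),
                 lapply(fold_changes, function(fc) rtf_apply_fold_changes(pars, fc)))
  } else {
    if (!is.list(pars) || is.null(names(pars)) ||
        !all(vapply(pars, inherits, logical(1), "rtf_dose_params")))
      stop("'pars' must be an rtf_dose_params object or a named list of them")
    by_cond <- pars
  }
  t_range <- diff(range(times))
  grid <- expand.grid(time = times, dose = doses,
                      condition = names(by_cond),
                      replicate = seq_len(n_replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  mu <- numeric(nrow(grid))
  for (cond in names(by_cond)) {
    for (d in doses) {
      idx <- grid$condition == cond & grid$dose == d
      mu[idx] <- rtf_curve_dose(grid$time[idx], d, by_cond[[cond]], t_range)
    }
  }
  grid$value <- mu + with_seed(seed, stats::rnorm(nrow(grid), 0, sigma))
  out <- as_timecourse(grid)
  attr(out, "truth") <- by_cond
  attr(out, "sigma") <- sigma
  attr(out, "seed") <- seed
  out
}

#' Synthetic inflammasome-activation-like dataset
#'
#' Generates a two-condition dataset emulating a nigericin-stimulated
#' IL-1beta release ELISA design: 7 doses, 8 time points, 3 replicates,
#' sustained-only responses (`B = 0`, so the curve rises to a plateau with
#' no overshoot), with the sustained amplitude, rate and time shift all
#' dose-dependent, and a "knockout" condition whose response is weakened,
#' slowed and delayed relative to the "wildtype" reference through
#' fold-changes on `M_A`, `M_alpha`, `M_tau`, `K_A` and `h_alpha`.  All
#' numbers are synthetic; the generating truth is attached as an attribute.
#'
#' @param seed integer seed (default 1).
#' @param sigma noise SD; by default 2\% of the noise-free response range
#'   of the design (about 0.017 response units).
#' @param n_replicates replicates per cell (default 3).
#' @param knockout logical: include the perturbed condition (default TRUE)?
#' @return an [as_timecourse()] data frame with attributes `"truth"`
#'   (generating parameters per condition), `"fold_changes"`, `"sigma"`
#'   and `"seed"`.
#' @export
simulate_inflammasome <- function(seed = 1, sigma = NULL, n_replicates = 3,
                                  knockout = TRUE) {
  wt <- rtf_dose_params(
    A     = rtf_hill_triplet(M = 1.0, K = 4, h = 2),
    B     = 0,
    alpha = rtf_hill_triplet(M = 0.8, K = 3, h = 2),
    beta  = 0.8,   # unused: B = 0
    gamma = 0.8,   # unused: B = 0
    tau   = rtf_hill_triplet(M = 2.0, K = 5, h = 2),
    b     = 0.05,
    sigma = 1)
  doses <- c(1, 2, 3, 4, 5, 6, 10)
  times <- c(0, 1, 2, 3, 4, 6, 8, 10)
  # default noise: 2% of the noise-free response range of this design
  if (is.null(sigma)) {
    surface <- vapply(doses, function(d)
      rtf_curve_dose(times, d, wt, diff(range(times))), numeric(length(times)))
    sigma <- 0.02 * diff(range(surface))
  }
  wt$sigma <- max(sigma, 1e-10)
  fc <- list(knockout = c(M_A = 0.4, M_alpha = 0.6, M_tau = 1.5,
                          K_A = 1.5, h_alpha = 0.7))
  out <- simulate_timecourse(
    wt,
    doses = doses,
    times = times,
    n_replicates = n_replicates, sigma = sigma,
    fold_changes = if (knockout) fc else NULL,
    reference = "wildtype", seed = seed)
  attr(out, "fold_changes") <- if (knockout) fc else NULL
  out
}

# run expr under a temporary RNG state seeded with `seed` (NULL = use the
# current stream); the caller's .Random.seed is restored afterwards
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' @export
print.rtf_data <- function(x, ...) {
  cat("Time-course dataset: ", nrow(x), " measurements, ",
      length(unique(x$time)), " time points, ",
      length(unique(x$dose)), " dose(s), conditions: ",
      paste(unique(x$condition), collapse = ", "), "\n", sep = "")
  cat("time range T = ", time_range(x), "\n", sep = "")
  NextMethod()
}
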