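# Scan-level mixture model. For matched template isotope indices s and
# components i (ordered by mass), the model matrix places component i's
# theoretical abundances with a row offset of omega_{i-1} cumulative
# integer-Da shifts:
#   T[s, i] = d_{s - omega_{i-1}, i}  if s > omega_{i-1}, else 0,
# restricted to the matched rows and with each column renormalised to sum
# one. The normalised envelope O_j is then modelled as
#   O_j = sum_i T_i * exp(theta_i),
# with unconstrained theta (the exponential enforces strictly positive
# mixture contributions), fitted by Levenberg-Marquardt least squares.

#' Fitting options
#'
#' @param max_iterations Maximum Levenberg-Marquardt iterations.
#' @param ftol,ptol,gtol Relative tolerances on the reduction of the sum of
#'   squares, the parameter step, and the gradient-residual orthogonality.
#' @param min_points_over_params Minimum excess of matched peaks over the
#'   number of components required to attempt a fit (`n >= p + excess`).
#' @return A list of class `fit_options`.
#' @export
fit_options <- function(max_iterations = 200, ftol = 1e-10, ptol = 1e-10,
                        gtol = 1e-10, min_points_over_params = 1L) {
  structure(list(max_iterations = max_iterations, ftol = ftol, ptol = ptol,
                 gtol = gtol,
                 min_points_over_params = as.integer(min_points_over_params)),
            class = "fit_options")
}

#' Build the scan-specific model matrix
#'
#' Restricts the shifted theoretical templates to the matched isotope rows
#' of one scan and renormalises every column to sum one. Because the set of
#' matched rows varies, the matrix can change from scan to scan.
#'
#' @param patterns An `isotope_pattern_set`.
#' @param matched_iso_idx Strictly increasing 1-based template isotope
#'   indices with an experimental match.
#' @return A list of class `model_matrix`: `t` (n x p numeric matrix),
#'   `row_iso_idx`, `col_labels`, and `unobservable` — labels of components
#'   whose column is entirely zero on these rows (such a scan cannot be
#'   fitted).
#' @export
build_model_matrix <- function(patterns, matched_iso_idx) {
  stopifnot(inherits(patterns, "isotope_pattern_set"))
  s <- as.integer(matched_iso_idx)
  if (length(s) == 0L)
    stop("matched_iso_idx must be non-empty", call. = FALSE)
  if (is.unsorted(s, strictly = TRUE) || any(s < 1L) || any(s > patterns$n_peaks))
    stop("matched_iso_idx must be strictly increasing indices within the ",
         "template range", call. = FALSE)
  p <- length(patterns$components)
  omega0 <- c(0L, patterns$omegas)      # omega_0 = 0 for the lightest
  tm <- matrix(0, length(s), p,
               dimnames = list(NULL, patterns$components))
  unobservable <- character(0)
  for (i in seq_len(p)) {
    src <- s - omega0[i]
    ok <- src >= 1L
    tm[ok, i] <- patterns$d_theor[src[ok], i]
    colsum <- sum(tm[, i])
    if (colsum > 0) {
      tm[, i] <- tm[, i] / colsum
    } else {
      unobservable <- c(unobservable, patterns$components[i])
    }
  }
  structure(list(t = tm, row_iso_idx = s, col_labels = patterns$components,
                 unobservable = unobservable),
            class = "model_matrix")
}

.skipped_fit <- function(rt, tic, n_obs, status) {
  structure(list(rt = rt, tic = tic, theta = NULL, coeffs = NULL,
                 residuals = NULL, rss = NA_real_, n_obs = n_obs,
                 converged = FALSE, status = status), class = "scan_fit")
}

#' Fit the mixture model to one matched envelope
#'
#' Minimises the residual sum of squares of
#' `O_j - sum_i T_i exp(theta_i)` with Levenberg-Marquardt, initialised at
#' `theta_i = log(1/p)` (equal contributions). The exponential
#' reparametrisation keeps every component contribution strictly positive;
#' an absent component is represented by `theta -> -Inf`, i.e. a coefficient
#' indistinguishable from zero.
#'
#' Scans with an empty envelope, with fewer matched peaks than
#' `p + min_points_over_params`, or on which some component's shifted
#' template vanishes entirely, are returned with a `skipped_*` status
#' instead of an unidentifiable fit.
#'
#' @param envelope A `matched_envelope`.
#' @param patterns An `isotope_pattern_set`.
#' @param opts A [fit_options()] list.
#' @return A `scan_fit`: `rt`, `tic`, `theta`, `coeffs` (`exp(theta)`,
#'   named by component), `residuals`, `rss`, `n_obs`, `converged` and
#'   `status` (one of `fitted`, `skipped_empty`, `skipped_underdetermined`,
#'   `not_converged`).
#' @export
fit_scan <- function(envelope, patterns, opts = fit_options()) {
  stopifnot(inherits(envelope, "matched_envelope"))
  p <- length(patterns$components)
  if (envelope$n == 0L)
    return(.skipped_fit(envelope$scan_rt, 0, 0L, "skipped_empty"))
  if (envelope$n < p + opts$min_points_over_params)
    return(.skipped_fit(envelope$scan_rt, envelope$tic, envelope$n,
                        "skipped_underdetermined"))
  mm <- build_model_matrix(patterns, envelope$matched_iso_idx)
  if (length(mm$unobservable))
    return(.skipped_fit(envelope$scan_rt, envelope$tic, envelope$n,
                        "skipped_underdetermined"))
  tm <- mm$t
  o <- envelope$o
  res_fn <- function(theta) o - as.vector(tm %*% exp(theta))
  jac_fn <- function(theta) -tm * rep(exp(theta), each = nrow(tm))
  fit <- minpack.lm::nls.lm(
    par = rep(log(1 / p), p), fn = res_fn, jac = jac_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = opts$max_iterations, ftol = opts$ftol, ptol = opts$ptol,
      gtol = opts$gtol))
  converged <- fit$info %in% 1:4
  coeffs <- exp(fit$par)
  names(coeffs) <- patterns$components
  structure(list(
    rt = envelope$scan_rt, tic = envelope$tic, theta = fit$par,
    coeffs = coeffs, residuals = res_fn(fit$par),
    rss = sum(res_fn(fit$par)^2), n_obs = envelope$n,
    converged = converged,
    status = if (converged) "fitted" else "not_converged"
  ), class = "scan_fit")
}

#' Fit every scan of a run
#'
#' Loops the alignment + fit over all mass scans of a run, in retention-time
#' order. Per-scan failures (empty or underdetermined envelopes,
#' non-convergence) are recorded as statuses, never raised as errors, so a
#' single bad scan cannot abort a run.
#'
#' @param run An `lcms_run`.
#' @param patterns An `isotope_pattern_set`.
#' @param windows Optional `alignment_windows`; built from `patterns` with
#'   `ppm` when omitted.
#' @param opts A [fit_options()] list.
#' @param ppm Mass accuracy used when `windows` is `NULL`.
#' @return A list of `scan_fit` objects (class `scan_fit_list`), one per
#'   scan, with a `summary` attribute counting fitted / skipped /
#'   non-converged scans.
#' @export
fit_run <- function(run, patterns, windows = NULL, opts = fit_options(),
                    ppm = 10) {
  stopifnot(inherits(run, "lcms_run"))
  if (is.null(windows)) windows <- build_windows(patterns, ppm)
  fits <- lapply(run$scans, function(sc)
    fit_scan(match_scan(sc, windows), patterns, opts))
  status <- vapply(fits, `[[`, character(1), "status")
  attr(fits, "summary") <- table(factor(
    status, levels = c("fitted", "not_converged", "skipped_empty",
                       "skipped_underdetermined")))
  class(fits) <- "scan_fit_list"
  fits
}

#' @export
print.scan_fit_list <- function(x, ...) {
  s <- attr(x, "summary")
  cat("<scan_fit_list> ", length(x), " scans: ",
      paste(names(s), as.integer(s), sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' Per-scan fit table
#'
#' @param x A `scan_fit_list`.
#' @param ... Ignored.
#' @return A data.frame with `rt`, `tic`, `status`, `rss` and one
#'   coefficient column per component (NA for skipped scans).
#' @export
as.data.frame.scan_fit_list <- function(x, ...) {
  labels <- NULL
  for (f in x) if (!is.null(f$coeffs)) { labels <- names(f$coeffs); break }
  df <- data.frame(
    rt = vapply(x, `[[`, numeric(1), "rt"),
    tic = vapply(x, `[[`, numeric(1), "tic"),
    status = vapply(x, `[[`, character(1), "status"),
    rss = vapply(x, `[[`, numeric(1), "rss"))
  for (lab in labels)
    df[[paste0("coef_", lab)]] <- vapply(x, function(f)
      if (is.null(f$coeffs)) NA_real_ else unname(f$coeffs[lab]), numeric(1))
  df
}
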