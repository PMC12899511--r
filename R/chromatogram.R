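# Deconvoluted extracted ion chromatograms (DICs): the per-scan mixture
# coefficients scaled by the scan's matched TIC give each component's
# elution profile, S_j * exp(theta_hat_i_j) against r_j. Trapezoid areas of
# these profiles yield the relative quantification.

#' Assemble per-component DICs from scan fits
#'
#' Every scan contributes one point per component at its retention time:
#' height `S_j * exp(theta_hat_i_j)` for fitted scans and 0 for skipped
#' ones, so all DICs share the complete rt grid of the run (required for a
#' meaningful trapezoid integral).
#'
#' @param fits A `scan_fit_list` (or list of `scan_fit`) in rt order.
#' @param components Optional component labels; inferred from the first
#'   fitted scan when omitted.
#' @return A list of class `dic_set`; each element is a `dic` with
#'   `component`, `rt` and `height`.
#' @export
build_dics <- function(fits, components = NULL) {
  if (is.null(components)) {
    for (f in fits) if (!is.null(f$coeffs)) { components <- names(f$coeffs); break }
    if (is.null(components))
      stop("no fitted scan to infer component labels from; ",
           "pass `components` explicitly", call. = FALSE)
  }
  rt <- vapply(fits, `[[`, numeric(1), "rt")
  dics <- lapply(components, function(lab) {
    h <- vapply(fits, function(f) {
      if (is.null(f$coeffs)) 0 else f$tic * unname(f$coeffs[lab])
    }, numeric(1))
    structure(list(component = lab, rt = rt, height = h), class = "dic")
  })
  structure(dics, class = "dic_set")
}

#' Trapezoid area under a DIC
#'
#' @param dic A `dic` (component elution profile).
#' @return Area in intensity x minutes.
#' @export
integrate_dic <- function(dic) {
  if (length(dic$rt) < 2L)
    stop("need at least two chromatogram points to integrate", call. = FALSE)
  pracma::trapz(dic$rt, dic$height)
}

#' Mixture proportions from DIC areas
#'
#' The headline summary: each component's share of the total deconvoluted
#' signal, `p_hat_i = AUC_i / sum_l AUC_l`. When the scan fits are supplied
#' the residual trace `S_j - sum_i S_j exp(theta_hat_i_j)` — the part of
#' each scan's matched TIC the model does not attribute to any component —
#' is attached; a systematically positive trace flags unmodelled species.
#'
#' @param dics A `dic_set` from [build_dics()].
#' @param fits Optional `scan_fit_list` used to attach the residual trace
#'   and scan counts.
#' @return A list of class `quant_result`: `labels`, `aucs`, `proportions`,
#'   `n_scans_used`, and (if `fits` given) `residual_trace` (data.frame
#'   `rt`, `residual`).
#' @export
mixture_proportions <- function(dics, fits = NULL) {
  aucs <- vapply(dics, integrate_dic, numeric(1))
  labels <- vapply(dics, `[[`, character(1), "component")
  names(aucs) <- labels
  total <- sum(aucs)
  if (total <= 0)
    stop("all DIC areas are zero: no deconvoluted signal to quantify",
         call. = FALSE)
  props <- aucs / total
  residual_trace <- NULL
  n_used <- NA_integer_
  if (!is.null(fits)) {
    heights <- sapply(dics, `[[`, "height")
    tic <- vapply(fits, `[[`, numeric(1), "tic")
    residual_trace <- data.frame(
      rt = vapply(fits, `[[`, numeric(1), "rt"),
      residual = tic - rowSums(as.matrix(heights)))
    n_used <- sum(vapply(fits, `[[`, character(1), "status") == "fitted")
  }
  structure(list(labels = labels, aucs = aucs, proportions = props,
                 n_scans_used = n_used, residual_trace = residual_trace),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat("<quant_result>", if (!is.na(x$n_scans_used))
    paste0(" (", x$n_scans_used, " fitted scans)"), "\n", sep = "")
  for (i in seq_along(x$labels))
    cat(sprintf("  %-14s AUC %.4g   proportion %.4f (%.2f%%)\n",
                x$labels[i], x$aucs[i], x$proportions[i],
                100 * x$proportions[i]))
  invisible(x)
}

#' Naive monoisotopic-ratio baseline (two components)
#'
#' The simple estimate a practitioner might compute by hand for a pair of
#' species separated by `omega_1` isotopes: per scan, component 1's amount
#' from the intensity at template isotope 1 (its monoisotopic peak, which
#' the heavier component cannot reach), and component 2's amount from the
#' intensity at template isotope `omega_1 + 1` after subtracting the
#' contribution component 1's own envelope predicts there. Scans are
#' aggregated by a matched-TIC-weighted mean. This is a deliberately crude
#' baseline — it uses two isotope peaks per scan instead of the whole
#' envelope — shipped for comparison with the full deconvolution.
#'
#' @param envelopes List of `matched_envelope` (from [match_run()]).
#' @param patterns An `isotope_pattern_set` with exactly two components and
#'   `omega_1 >= 1`.
#' @return Named numeric vector of the two estimated proportions.
#' @export
naive_monoisotopic_estimate <- function(envelopes, patterns) {
  p <- length(patterns$components)
  if (p != 2L)
    stop("the monoisotopic-ratio baseline is defined for exactly two ",
         "components", call. = FALSE)
  w1 <- patterns$omegas[1]
  if (w1 < 1L)
    stop("components share a monoisotopic position (zero integer shift); ",
         "the baseline is degenerate", call. = FALSE)
  d <- patterns$d_theor
  if (d[1, 2] <= 0)
    stop("component 2 has zero theoretical abundance at its monoisotopic ",
         "position; the correction is degenerate", call. = FALSE)
  est <- 0
  wsum <- 0
  used <- 0L
  for (e in envelopes) {
    i1 <- match(1L, e$matched_iso_idx)
    i2 <- match(w1 + 1L, e$matched_iso_idx)
    if (is.na(i1) || is.na(i2) || e$tic <= 0) next
    int1 <- e$intensity_matched[i1]
    int2 <- e$intensity_matched[i2]
    # component 1's predicted intensity at isotope omega_1 + 1
    pred <- if (w1 + 1L <= nrow(d)) int1 * d[w1 + 1L, 1] / d[1, 1] else 0
    a1 <- int1 / d[1, 1]
    a2 <- max(int2 - pred, 0) / d[1, 2]
    if (a1 + a2 <= 0) next
    est <- est + e$tic * a1 / (a1 + a2)
    wsum <- wsum + e$tic
    used <- used + 1L
  }
  if (used == 0L)
    stop("no scan had both monoisotopic peaks matched", call. = FALSE)
  p1 <- est / wsum
  out <- c(p1, 1 - p1)
  names(out) <- patterns$components
  out
}
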