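# Per-scan envelope extraction: experimental centroids are matched to ppm
# windows centred on the lightest component's theoretical isotope grid (the
# first column of mz_theor). Heavier components are reached implicitly
# through their integer-Da row shifts in the model matrix, so only this one
# grid is ever matched against.

#' Build ppm alignment windows from a pattern set
#'
#' Creates the `n_peaks` mutually exclusive m/z intervals
#' `[b * (1 - ppm * 1e-6), b * (1 + ppm * 1e-6)]` around the lightest
#' component's theoretical isotope m/z values `b`. Mutual exclusivity is a
#' hard requirement: overlapping windows would make peak-to-isotope
#' assignment ambiguous, so an overlap raises an error reporting the
#' largest admissible tolerance.
#'
#' @param patterns An `isotope_pattern_set`.
#' @param ppm Mass accuracy in parts per million (half-width of each window
#'   relative to its centre).
#' @return An object of class `alignment_windows` with `centers`, `lower`,
#'   `upper` and `ppm`.
#' @export
build_windows <- function(patterns, ppm) {
  stopifnot(inherits(patterns, "isotope_pattern_set"))
  if (!is.numeric(ppm) || length(ppm) != 1L || ppm <= 0)
    stop("ppm must be a positive number", call. = FALSE)
  centers <- patterns$mz_theor[, 1]
  lower <- centers * (1 - ppm * 1e-6)
  upper <- centers * (1 + ppm * 1e-6)
  if (length(centers) > 1L) {
    gap <- which(upper[-length(upper)] >= lower[-1])
    if (length(gap)) {
      s <- gap[1]
      # max delta: b_s (1 + d) < b_{s+1} (1 - d)
      dmax <- 1e6 * min((centers[-1] - centers[-length(centers)]) /
                          (centers[-1] + centers[-length(centers)]))
      stop(sprintf(paste0(
        "alignment windows %d and %d overlap at %.2f ppm; ",
        "maximum admissible mass accuracy for this charge state is %.2f ppm"),
        s, s + 1L, ppm, dmax), call. = FALSE)
    }
  }
  structure(list(centers = centers, lower = lower, upper = upper, ppm = ppm),
            class = "alignment_windows")
}

#' Match one scan's centroids to alignment windows
#'
#' For each window, the most intense centroid inside it is assigned to the
#' corresponding theoretical isotope (intensity ties go to the peak closest
#' to the window centre, then to the lower m/z). Windows with no centroid
#' are dropped together with their isotope index. The matched intensities
#' are summed into the scan's matched TIC `S_j` and normalised to the
#' sum-to-one envelope `O_j`, the response vector of the deconvolution
#' model.
#'
#' @param scan A scan from an `lcms_run` (fields `rt`, `mz`, `intensity`).
#' @param windows An `alignment_windows` object.
#' @return An object of class `matched_envelope`: `scan_rt`,
#'   `matched_iso_idx` (1-based template isotope indices), `mz_matched`,
#'   `intensity_matched`, `tic`, `o` (normalised intensities) and `n`.
#'   `n = 0` (empty envelope) is a valid result.
#' @export
match_scan <- function(scan, windows) {
  stopifnot(inherits(windows, "alignment_windows"))
  nt <- length(windows$centers)
  idx <- integer(0)
  mzm <- numeric(0)
  im <- numeric(0)
  if (length(scan$mz)) {
    lo <- findInterval(windows$lower, scan$mz) + 1L
    hi <- findInterval(windows$upper, scan$mz)
    for (s in seq_len(nt)) {
      if (lo[s] > hi[s]) next
      cand <- lo[s]:hi[s]
      ints <- scan$intensity[cand]
      best <- cand[ints == max(ints)]
      if (length(best) > 1L) {
        dist <- abs(scan$mz[best] - windows$centers[s])
        best <- best[dist == min(dist)]
        best <- best[1L]          # lowest m/z among remaining ties
      }
      idx <- c(idx, s)
      mzm <- c(mzm, scan$mz[best])
      im <- c(im, scan$intensity[best])
    }
  }
  tic <- sum(im)
  structure(list(
    scan_rt = scan$rt,
    matched_iso_idx = idx,
    mz_matched = mzm,
    intensity_matched = im,
    tic = tic,
    o = if (length(im) && tic > 0) im / tic else numeric(0),
    n = length(idx)
  ), class = "matched_envelope")
}

#' Match every scan of a run
#'
#' @param run An `lcms_run`.
#' @param windows An `alignment_windows`.
#' @return List of `matched_envelope`, one per scan in rt order.
#' @export
match_run <- function(run, windows) {
  lapply(run$scans, match_scan, windows = windows)
}

#' Per-match alignment diagnostics
#'
#' Flat table of every matched centroid across a run: expected and observed
#' m/z, the signed ppm error and the intensity — the table to inspect when
#' judging whether the chosen mass accuracy fits the instrument.
#'
#' @param envelopes List of `matched_envelope` (from [match_run()]).
#' @param windows The `alignment_windows` used for matching.
#' @return A data.frame with columns `rt`, `iso_idx`, `mz_expected`,
#'   `mz_observed`, `ppm_error`, `intensity`.
#' @export
alignment_diagnostics <- function(envelopes, windows) {
  rows <- lapply(envelopes, function(e) {
    if (e$n == 0L) return(NULL)
    exp_mz <- windows$centers[e$matched_iso_idx]
    data.frame(rt = e$scan_rt, iso_idx = e$matched_iso_idx,
               mz_expected = exp_mz, mz_observed = e$mz_matched,
               ppm_error = 1e6 * (e$mz_matched - exp_mz) / exp_mz,
               intensity = e$intensity_matched)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L)
    return(data.frame(rt = numeric(0), iso_idx = integer(0),
                      mz_expected = numeric(0), mz_observed = numeric(0),
                      ppm_error = numeric(0), intensity = numeric(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
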