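# Containers for centroided LC-MS1 runs: a run is a retention-time-ordered
# list of scans, each scan a set of (m/z, intensity) centroids.

new_scan <- function(rt, mz, intensity) {
  stopifnot(length(mz) == length(intensity))
  if (is.unsorted(mz, strictly = TRUE)) {
    ord <- order(mz)
    mz <- mz[ord]
    intensity <- intensity[ord]
  }
  if (any(intensity < 0))
    stop("negative intensity in scan at rt ", rt, call. = FALSE)
  structure(list(rt = rt, mz = mz, intensity = intensity,
                 n_points = length(mz)), class = "ms_scan")
}

new_lcms_run <- function(scans, source = "in-memory") {
  if (length(scans) < 1L)
    stop("an LC-MS run needs at least one scan", call. = FALSE)
  rts <- vapply(scans, `[[`, numeric(1), "rt")
  if (is.unsorted(rts, strictly = TRUE))
    stop("scan retention times must be strictly increasing", call. = FALSE)
  structure(list(scans = scans, n_scans = length(scans), source = source),
            class = "lcms_run")
}

#' @export
print.lcms_run <- function(x, ...) {
  rts <- scan_rts(x)
  np <- vapply(x$scans, `[[`, integer(1), "n_points")
  cat("<lcms_run> ", x$n_scans, " MS1 scans, rt ",
      sprintf("%.3f-%.3f", min(rts), max(rts)), " min, ",
      sum(np), " centroids (", x$source, ")\n", sep = "")
  invisible(x)
}

#' Retention times of all scans in a run
#'
#' @param run An `lcms_run`.
#' @return Numeric vector of retention times in minutes, in scan order.
#' @export
scan_rts <- function(run) {
  vapply(run$scans, `[[`, numeric(1), "rt")
}

#' Read a centroided mzML file
#'
#' Reads MS1 scans from an mzML file (plain or gzipped, via mzR/proteowizard)
#' into an [`lcms_run`][read_mzml]. Retention times are converted from the
#' mzML convention (seconds) to minutes; peaks are sorted by m/z and
#' zero-intensity centroids are dropped.
#'
#' @param path Path to an mzML file.
#' @param ms_level MS level to retain (default 1).
#' @param allow_profile If `FALSE` (default), scans flagged as profile mode
#'   raise an error; set `TRUE` to read them as-is.
#' @return An `lcms_run`.
#' @export
read_mzml <- function(path, ms_level = 1L, allow_profile = FALSE) {
  if (!file.exists(path))
    stop("mzML file not found: ", path, call. = FALSE)
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  keep <- which(hdr$msLevel == ms_level)
  if (length(keep) == 0L)
    stop("no MS level-", ms_level, " scans in ", path, call. = FALSE)
  if (!allow_profile && !is.null(hdr$centroided) &&
      any(!is.na(hdr$centroided[keep]) & !hdr$centroided[keep]))
    stop("profile-mode spectra found; centroid the data first or pass ",
         "allow_profile = TRUE", call. = FALSE)
  scans <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    pk <- mzR::peaks(handle, keep[k])
    nz <- pk[, 2] > 0
    scans[[k]] <- new_scan(rt = hdr$retentionTime[keep[k]] / 60,
                           mz = pk[nz, 1], intensity = pk[nz, 2])
  }
  new_lcms_run(scans, source = path)
}

#' Restrict a run to a retention-time window
#'
#' @param run An `lcms_run`.
#' @param rt_min,rt_max Window bounds in minutes (inclusive).
#' @return An `lcms_run` containing the scans with
#'   `rt_min <= rt <= rt_max`.
#' @export
restrict_rt <- function(run, rt_min, rt_max) {
  stopifnot(rt_min < rt_max)
  rts <- scan_rts(run)
  keep <- rts >= rt_min & rts <= rt_max
  if (!any(keep))
    stop("no scans fall within [", rt_min, ", ", rt_max, "] min",
         call. = FALSE)
  new_lcms_run(run$scans[keep], source = run$source)
}
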