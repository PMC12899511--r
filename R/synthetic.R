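# Ground-truth LC-MS1 simulator: known components with Gaussian elution
# profiles, centroids placed at the true aggregated-variant m/z of each
# component (not the integer-Da approximation), near-coincident centroids
# merged as a centroiding instrument would, optional ppm-scale m/z jitter
# and intensity noise. Every run carries its exact generation ground truth,
# so the full pipeline can be validated without proprietary data.

#' Describe one simulated mixture component
#'
#' @param composition Elemental composition (object or formula string).
#' @param amount Relative amount: the component's share of total generated
#'   ion current is `amount / sum(amounts)`.
#' @param rt_center,rt_sigma Gaussian elution centre and width, minutes.
#' @param label Component label.
#' @return A list of class `sim_component`.
#' @export
sim_component <- function(composition, amount, rt_center, rt_sigma,
                          label = NULL) {
  composition <- as_composition(composition)
  stopifnot(amount >= 0, rt_sigma > 0)
  structure(list(composition = composition, amount = amount,
                 rt_center = rt_center, rt_sigma = rt_sigma,
                 label = label %||% format(composition)),
            class = "sim_component")
}

#' Specify a synthetic LC-MS1 run
#'
#' Defaults emulate a small-molecule-therapeutics QC acquisition: 1 Hz MS1
#' scans over a few minutes around the elution window, negative-mode ESI at
#' a single charge state, ppm-scale mass jitter.
#'
#' @param components List of [sim_component()] objects (at least one with
#'   `amount > 0`).
#' @param charge Charge state z used for all components.
#' @param polarity `"negative"` or `"positive"`.
#' @param rt_range Length-2 vector, run start/end in minutes.
#' @param sampling_rate Scan rate in Hz (default 1).
#' @param n_isotopes Aggregated variants generated per component envelope
#'   (default 30, enough to cover >99.9% of a 5-10 kDa envelope); each
#'   envelope is renormalised to sum one so `amount` is an ion-current
#'   share.
#' @param mz_jitter_ppm Gaussian sd of per-centroid relative m/z error, ppm.
#' @param intensity_noise `"none"`, `"gaussian"` (multiplicative, sd =
#'   `noise_cv` of the true intensity) or `"poisson"` (counts at
#'   `intensity / poisson_scale` ions).
#' @param noise_cv Coefficient of variation for Gaussian intensity noise.
#' @param poisson_scale Intensity units per ion for Poisson noise.
#' @param base_intensity Peak height scale of a unit-amount component.
#' @param merge_ppm Centroids closer than this (relative) are merged into
#'   one weighted-mean peak, emulating instrument centroiding of unresolved
#'   neighbours.
#' @param seed Integer seed; two runs from the same spec are identical.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(components, charge, polarity = c("negative", "positive"),
                     rt_range = c(8, 12), sampling_rate = 1,
                     n_isotopes = 30, mz_jitter_ppm = 0,
                     intensity_noise = c("none", "gaussian", "poisson"),
                     noise_cv = 0.05, poisson_scale = 1,
                     base_intensity = 1e6, merge_ppm = 10, seed = 1L) {
  polarity <- match.arg(polarity)
  intensity_noise <- match.arg(intensity_noise)
  if (inherits(components, "sim_component")) components <- list(components)
  stopifnot(length(components) >= 1L, sampling_rate > 0,
            length(rt_range) == 2L, rt_range[1] < rt_range[2])
  amounts <- vapply(components, `[[`, numeric(1), "amount")
  if (all(amounts == 0))
    stop("at least one component must have a positive amount", call. = FALSE)
  structure(list(components = components, charge = as.integer(charge),
                 polarity = polarity, rt_range = rt_range,
                 sampling_rate = sampling_rate,
                 n_isotopes = as.integer(n_isotopes),
                 mz_jitter_ppm = mz_jitter_ppm,
                 intensity_noise = intensity_noise, noise_cv = noise_cv,
                 poisson_scale = poisson_scale,
                 base_intensity = base_intensity, merge_ppm = merge_ppm,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic LC-MS1 run with ground truth
#'
#' @param spec A [sim_spec()].
#' @return A list of class `sim_run`: `run` (an `lcms_run`), and `truth`
#'   with `labels`, `ion_counts` (total noiseless generated intensity per
#'   component), `proportions`, and `per_scan` (matrix of per-scan
#'   noiseless component ion counts).
#' @export
simulate_run <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  .with_seed(spec$seed, {
    comps <- spec$components
    pcount <- length(comps)
    labels <- vapply(comps, `[[`, character(1), "label")
    z <- spec$charge
    # per-component true envelope (normalised to sum one) and m/z grid
    env <- lapply(comps, function(cm) {
      b <- brain_distribution(cm$composition, spec$n_isotopes)
      ab <- b$abundances / sum(b$abundances)
      mz <- if (spec$polarity == "negative")
        (b$masses - z * .mass_proton) / z
      else (b$masses + z * .mass_proton) / z
      list(mz = mz, ab = ab)
    })
    step <- 1 / (spec$sampling_rate * 60)
    rts <- seq(spec$rt_range[1], spec$rt_range[2], by = step)
    per_scan <- matrix(0, length(rts), pcount,
                       dimnames = list(NULL, labels))
    scans <- vector("list", length(rts))
    for (j in seq_along(rts)) {
      rt <- rts[j]
      mz_all <- numeric(0)
      int_all <- numeric(0)
      for (i in seq_len(pcount)) {
        cm <- comps[[i]]
        h <- cm$amount * spec$base_intensity *
          exp(-(rt - cm$rt_center)^2 / (2 * cm$rt_sigma^2))
        ints <- h * env[[i]]$ab
        per_scan[j, i] <- sum(ints)
        mz_all <- c(mz_all, env[[i]]$mz)
        int_all <- c(int_all, ints)
      }
      ord <- order(mz_all)
      mz_all <- mz_all[ord]
      int_all <- int_all[ord]
      # merge unresolved neighbours (weighted-mean m/z, summed intensity)
      if (length(mz_all) > 1L && spec$merge_ppm > 0) {
        gap_ok <- diff(mz_all) / mz_all[-length(mz_all)] >
          spec$merge_ppm * 1e-6
        grp <- cumsum(c(TRUE, gap_ok))
        int_m <- as.vector(tapply(int_all, grp, sum))
        mz_m <- as.vector(tapply(mz_all * int_all, grp, sum)) / int_m
        mz_all <- mz_m
        int_all <- int_m
      }
      if (spec$mz_jitter_ppm > 0)
        mz_all <- mz_all * (1 + stats::rnorm(length(mz_all)) *
                              spec$mz_jitter_ppm * 1e-6)
      int_all <- switch(spec$intensity_noise,
        none = int_all,
        gaussian = pmax(int_all * (1 + stats::rnorm(length(int_all)) *
                                     spec$noise_cv), 0),
        poisson = stats::rpois(length(int_all),
                               int_all / spec$poisson_scale) *
          spec$poisson_scale)
      keep <- int_all > 0
      scans[[j]] <- new_scan(rt, mz_all[keep], int_all[keep])
    }
    ion_counts <- colSums(per_scan)
    structure(list(
      run = new_lcms_run(scans, source = "simulated"),
      truth = list(labels = labels, ion_counts = ion_counts,
                   proportions = ion_counts / sum(ion_counts),
                   per_scan = per_scan)
    ), class = "sim_run")
  })
}

#' Expected mixture percentages from a volumetric design
#'
#' For two stock solutions mixed at volumes `b` and `c`, the expected
#' percentage of the first species is `100 * b / (b + c)`, reported to two
#' decimals — the arithmetic behind a serial-dilution calibration design.
#'
#' @param b,c Non-negative volumes (vectorised).
#' @return Numeric vector of percentages, rounded to 2 decimals.
#' @examples
#' design_percentages(c(1, 1, 8), c(1, 16, 1))
#' @export
design_percentages <- function(b, c) {
  stopifnot(length(b) == length(c))
  if (any(b < 0 | c < 0))
    stop("volumes must be non-negative", call. = FALSE)
  if (any(b + c == 0))
    stop("both volumes zero in at least one row", call. = FALSE)
  round(100 * b / (b + c), 2)
}

#' Two-strand calibration design
#'
#' The 15 volume ratios of a two-oligonucleotide calibration series
#' spanning 0-100%, with the expected percentage of the first strand
#' computed by [design_percentages()].
#'
#' @return A data.frame with columns `vol_b`, `vol_c`, `ratio` and
#'   `expected_pct_b`.
#' @export
bc_mixing_design <- function() {
  vol_b <- c(0, 1, 1, 1, 1, 1, 1, 1, 2, 4, 8, 16, 40, 80, 1)
  vol_c <- c(1, 80, 40, 16, 8, 4, 2, 1, 1, 1, 1, 1, 1, 1, 0)
  data.frame(vol_b = vol_b, vol_c = vol_c,
             ratio = paste(vol_b, vol_c, sep = ":"),
             expected_pct_b = design_percentages(vol_b, vol_c))
}

#' Write a run to a centroided mzML file
#'
#' Writes an `lcms_run` as standard MS1 mzML (via mzR/proteowizard),
#' readable back with [read_mzml()] and by external viewers.
#'
#' @param run An `lcms_run`.
#' @param path Output file path (`.mzML`).
#' @param polarity `"negative"` or `"positive"` (stored per spectrum).
#' @return The path, invisibly.
#' @export
write_mzml <- function(run, path, polarity = c("negative", "positive")) {
  stopifnot(inherits(run, "lcms_run"))
  polarity <- match.arg(polarity)
  pol <- if (polarity == "negative") 0L else 1L
  n <- run$n_scans
  pks <- lapply(run$scans, function(sc)
    cbind(mz = sc$mz, intensity = sc$intensity))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = pol,
    peaksCount = vapply(run$scans, `[[`, integer(1), "n_points"),
    totIonCurrent = vapply(run$scans, function(sc) sum(sc$intensity),
                           numeric(1)),
    retentionTime = scan_rts(run) * 60,
    basePeakMZ = vapply(run$scans, function(sc)
      if (sc$n_points) sc$mz[which.max(sc$intensity)] else 0, numeric(1)),
    basePeakIntensity = vapply(run$scans, function(sc)
      if (sc$n_points) max(sc$intensity) else 0, numeric(1)),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = vapply(run$scans, function(sc)
      if (sc$n_points) min(sc$mz) else 0, numeric(1)),
    highMZ = vapply(run$scans, function(sc)
      if (sc$n_points) max(sc$mz) else 0, numeric(1)),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_, scanWindowLowerLimit = NA_real_,
    scanWindowUpperLimit = NA_real_)
  mzR::writeMSData(pks, file = path, header = hdr, outformat = "mzml")
  invisible(path)
}
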