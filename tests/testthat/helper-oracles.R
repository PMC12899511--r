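# Independent oracles used across the suite. The fine-structure enumerator
# computes aggregated isotope distributions by explicit multinomial
# enumeration of isotopologues — a completely different route from the
# package's polynomial recurrence — and is only feasible for small
# molecules (<= ~30 atoms), which is exactly where it serves as the truth.

iso_table <- function() dicquant:::.isotope_table

# all ways to put n atoms into k isotope bins (k small)
.compositions_of <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- list()
  for (i in 0:n) {
    sub <- .compositions_of(n - i, k - 1L)
    out[[length(out) + 1L]] <- cbind(i, sub)
  }
  do.call(rbind, out)
}

# aggregated (by neutron count) distribution of n atoms of one element:
# list(prob, mom) vectors indexed by neutron count + 1; mom = prob * mass
enum_element_dist <- function(el, n, max_neutrons) {
  iso <- iso_table()[[el]]
  k <- length(iso$abundance)
  shifts <- round(iso$mass - iso$mass[1])
  prob <- numeric(max_neutrons + 1L)
  mom <- numeric(max_neutrons + 1L)
  combos <- .compositions_of(n, k)
  for (r in seq_len(nrow(combos))) {
    cnt <- combos[r, ]
    neut <- sum(cnt * shifts)
    if (neut > max_neutrons) next
    pr <- stats::dmultinom(cnt, prob = iso$abundance)
    prob[neut + 1L] <- prob[neut + 1L] + pr
    mom[neut + 1L] <- mom[neut + 1L] + pr * sum(cnt * iso$mass)
  }
  list(prob = prob, mom = mom)
}

.convolve_dist <- function(a, b, max_neutrons) {
  n <- max_neutrons + 1L
  prob <- numeric(n)
  mom <- numeric(n)
  for (i in seq_len(n)) {
    if (a$prob[i] == 0 && a$mom[i] == 0) next
    for (j in seq_len(n - i + 1L)) {
      if (b$prob[j] == 0 && b$mom[j] == 0) next
      k <- i + j - 1L
      prob[k] <- prob[k] + a$prob[i] * b$prob[j]
      # E[mass of sum] accumulates cross-wise
      mom[k] <- mom[k] + a$prob[i] * b$mom[j] + b$prob[j] * a$mom[i]
    }
  }
  list(prob = prob, mom = mom)
}

# brute-force aggregated distribution of a small molecule
enum_distribution <- function(formula, n_peaks) {
  counts <- parse_composition(formula)$counts
  dist <- list(prob = c(1, numeric(n_peaks - 1L)),
               mom = c(0, numeric(n_peaks - 1L)))
  for (el in names(counts)) {
    ed <- enum_element_dist(el, counts[[el]], n_peaks - 1L)
    dist <- .convolve_dist(dist, ed, n_peaks - 1L)
  }
  list(masses = ifelse(dist$prob > 0, dist$mom / dist$prob, NA_real_),
       abundances = dist$prob)
}

# hand-built pattern set with fully controlled template abundances, for
# structural model-matrix tests (values need not come from any molecule)
toy_pattern_set <- function(d_theor, deltas, labels = NULL) {
  p <- ncol(d_theor)
  nt <- nrow(d_theor)
  labels <- labels %||% LETTERS[seq_len(p)]
  mono <- 7000 + c(0, cumsum(deltas))
  mw <- vapply(seq_len(p), function(i) mono[i] + (seq_len(nt) - 1) * 1.003,
               numeric(nt))
  mw <- matrix(mw, nrow = nt, ncol = p)
  structure(list(
    components = labels, compositions = NULL,
    mw_theor = mw, d_theor = d_theor,
    mz_theor = (mw - 9 * 1.00727646688) / 9,
    n_peaks = nt, charge = 9L, polarity = "negative",
    deltas = as.integer(deltas),
    omegas = as.integer(cumsum(deltas))), class = "isotope_pattern_set")
}

toy_envelope <- function(o, iso_idx = seq_along(o), tic = 1000, rt = 10) {
  structure(list(scan_rt = rt, matched_iso_idx = as.integer(iso_idx),
                 mz_matched = numeric(length(o)),
                 intensity_matched = o * tic, tic = tic, o = o,
                 n = length(o)), class = "matched_envelope")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# canonical two-component oligonucleotide-like fixture: a fluorinated
# full-length product and its -HF +H2O (-2 Da) impurity
flp_composition <- function() parse_composition("C203H255N77O118P19S4F9")
impurity_composition <- function()
  composition_arith(flp_composition(), add = list("H2O"),
                    subtract = list("HF"))

two_component_patterns <- function(n_peaks = 20, charge = 9)
  build_pattern_set(list(flp_composition(), impurity_composition()),
                    n_peaks = n_peaks, charge = charge,
                    labels = c("FLP", "impurity"))

# spec for a two-component co-eluting run with a given impurity fraction
two_component_spec <- function(impurity_frac, seed = 1, noise = "none",
                               noise_cv = 0.05, jitter = 0,
                               rt_range = c(9, 11)) {
  sim_spec(
    components = list(
      sim_component(impurity_composition(), amount = impurity_frac,
                    rt_center = 9.85, rt_sigma = 0.15, label = "impurity"),
      sim_component(flp_composition(), amount = 1 - impurity_frac,
                    rt_center = 10.0, rt_sigma = 0.15, label = "FLP")),
    charge = 9, rt_range = rt_range, sampling_rate = 1,
    mz_jitter_ppm = jitter, intensity_noise = noise, noise_cv = noise_cv,
    seed = seed)
}

two_component_sim <- function(...) simulate_run(two_component_spec(...))

# construct a run directly from vectors (bypasses the simulator)
new_lcms_run_for_test <- function(rt, mz, intensity) {
  scans <- Map(dicquant:::new_scan, rt, mz, intensity)
  dicquant:::new_lcms_run(scans, source = "test")
}

# full pipeline on a simulated run: returns estimated proportions named by
# component label
quantify_sim <- function(sim, patterns, ppm = 10) {
  fits <- fit_run(sim$run, patterns, ppm = ppm)
  dics <- build_dics(fits, components = patterns$components)
  mixture_proportions(dics, fits)$proportions
}
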