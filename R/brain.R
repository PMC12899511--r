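# Aggregated theoretical isotope distributions via the BRAIN
# polynomial-recurrence scheme (Claesen et al., J Am Soc Mass Spectrom 2012).
#
# The compound generating polynomial is U(x) = prod_e Q_e(x)^{v_e}, where
# Q_e(x) = sum_i P_{e,i} x^{k_i} collects the isotope abundances of element e
# by neutron shift k_i, and v_e is the atom count. The coefficient q_j of x^j
# in U is the occupation probability of the aggregated variant with j extra
# neutrons. Writing U'/U = sum_e v_e Q_e'/Q_e and expanding around the
# inverse roots of the elemental polynomials gives the Newton-Girard
# recurrence
#   q_j = -(1/j) * sum_{l=1..j} phi_l * q_{j-l},   q_0 = prod_e P_{e,0}^{v_e},
# with phi_l = sum_e v_e sum_t r_{e,t}^{-l} the power sums over the roots
# r_{e,t} of Q_e. Centre masses come from the mass-moment series
# V(x) = U(x) * sum_e v_e R_e(x)/Q_e(x), R_e(x) = sum_i P_{e,i} m_{e,i} x^i,
# evaluated by truncated power-series division: mu_j = [x^j]V / q_j.

#' Aggregated isotope distribution of a composition
#'
#' Computes the first `n_peaks` aggregated isotope variants (grouped by
#' neutron count, not fine structure) of an elemental composition: their
#' occupation probabilities and abundance-weighted centre masses, using the
#' BRAIN Newton-Girard recurrence on the elemental generating polynomials.
#'
#' @param comp An `elemental_composition` or formula string.
#' @param n_peaks Number of aggregated variants to return (monoisotopic
#'   variant first).
#' @return A list with `masses` (Da, strictly increasing) and `abundances`
#'   (probabilities; they sum to at most 1 because the distribution is
#'   truncated at `n_peaks` variants).
#' @examples
#' brain_distribution("C100", n_peaks = 3)
#' @export
brain_distribution <- function(comp, n_peaks) {
  comp <- as_composition(comp)
  if (!is.numeric(n_peaks) || length(n_peaks) != 1L || n_peaks < 1)
    stop("n_peaks must be a positive integer", call. = FALSE)
  n_peaks <- as.integer(n_peaks)

  nt <- n_peaks
  phi <- numeric(nt)        # power sums over elemental polynomial roots
  q0_log <- 0
  mono <- 0
  # per-element abundance series inverses and mass-moment numerators
  ratio <- numeric(nt)      # coefficients of sum_e v_e R_e/Q_e, truncated
  for (el in names(comp$counts)) {
    v <- comp$counts[[el]]
    iso <- .isotope_table[[el]]
    # exponent = neutron count above the lightest isotope; not consecutive
    # for e.g. S (32/33/34/36), Cl (35/37), Br (79/81)
    shift <- round(iso$mass - iso$mass[1])
    deg <- max(shift)
    P <- numeric(deg + 1L)
    P[shift + 1L] <- iso$abundance
    M <- numeric(deg + 1L)
    M[shift + 1L] <- iso$mass
    mono <- mono + v * iso$mass[1]
    q0_log <- q0_log + v * log(P[1])
    if (deg >= 1L && nt > 1L) {
      # roots of Q_e(x) = P0 + P1 x + ... ; power sums of 1/r
      r <- polyroot(P)
      for (l in seq_len(nt - 1L))
        phi[l] <- phi[l] + v * Re(sum(r^(-l)))
    }
    # R_e/Q_e as a truncated power series (division by Q_e)
    Rc <- P * M                      # mass-moment polynomial coefficients
    inv <- numeric(nt)               # series of R_e/Q_e
    for (j in seq_len(nt) - 1L) {
      acc <- if (j <= deg) Rc[j + 1L] else 0
      if (j >= 1L) {
        lmax <- min(j, deg)
        if (lmax >= 1L)
          acc <- acc - sum(P[2:(lmax + 1L)] * inv[j - seq_len(lmax) + 1L])
      }
      inv[j + 1L] <- acc / P[1]
    }
    ratio <- ratio + v * inv
  }

  q <- numeric(nt)
  q[1] <- exp(q0_log)
  if (nt > 1L) {
    for (j in seq_len(nt - 1L))
      q[j + 1L] <- -sum(phi[seq_len(j)] * q[j:1]) / j
  }

  # mass moments: V = U * ratio (truncated product); mu_j = V_j / q_j
  mu <- numeric(nt)
  for (j in seq_len(nt) - 1L) {
    vj <- sum(q[seq_len(j + 1L)] * ratio[(j + 1L):1])
    # an unoccupied variant (q = 0, e.g. odd neutron counts of pure Cl_n)
    # has no centre mass; use the monoisotopic mass plus j times the 13C
    # neutron-gain as a placeholder to keep the grid monotone
    mu[j + 1L] <- if (q[j + 1L] > 0) vj / q[j + 1L] else
      mono + j * 1.00335483507
  }

  list(masses = mu, abundances = q)
}

#' Isotope pattern set for a list of mixture components
#'
#' Builds the theoretical template shared by all downstream steps: per
#' component the aggregated isotope masses (`mw_theor`), abundances
#' (`d_theor`) and m/z values (`mz_theor`), each an `n_peaks` x p matrix
#' with one column per component ordered by ascending monoisotopic mass.
#' The integer Da shifts between consecutive monoisotopic masses
#' (`deltas`, rounded to the nearest integer) and their cumulative sums
#' (`omegas`) encode how each heavier component's envelope is offset on the
#' lightest component's isotope grid.
#'
#' m/z conversion assumes the ESI proton transfer convention:
#' `(mass - z * m_p) / z` for negative polarity and `(mass + z * m_p) / z`
#' for positive, with the proton mass `m_p = 1.00727646688` Da.
#'
#' @param comps List of `elemental_composition` objects or formula strings,
#'   one per expected mixture component.
#' @param n_peaks Number of theoretical isotope variants per component
#'   (default 20). Must exceed the largest cumulative shift by at least 5 so
#'   every component contributes at least 5 template isotopes.
#' @param charge Positive integer charge state z.
#' @param polarity `"negative"` or `"positive"`.
#' @param labels Optional component labels; defaults to the canonical
#'   formula strings.
#' @return An object of class `isotope_pattern_set`.
#' @examples
#' build_pattern_set(list("C100H160N30O60P10", "C100H158N30O61P10"),
#'                   n_peaks = 15, charge = 5)
#' @export
build_pattern_set <- function(comps, n_peaks = 20, charge,
                              polarity = c("negative", "positive"),
                              labels = NULL) {
  polarity <- match.arg(polarity)
  if (inherits(comps, "elemental_composition") || is.character(comps))
    comps <- as.list(comps)
  comps <- lapply(comps, as_composition)
  p <- length(comps)
  stopifnot(p >= 1L)
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1)
    stop("charge must be a positive integer", call. = FALSE)
  charge <- as.integer(charge)

  if (is.null(labels)) {
    labels <- vapply(comps, format, character(1))
  } else if (length(labels) != p) {
    stop("labels must match the number of components", call. = FALSE)
  }

  mono <- vapply(comps, monoisotopic_mass, numeric(1))
  ord <- order(mono)
  comps <- comps[ord]
  labels <- labels[ord]
  mono <- mono[ord]

  deltas <- integer(0)
  if (p > 1L) {
    diffs <- diff(mono)
    # round half away from zero (diffs are non-negative here)
    deltas <- as.integer(floor(diffs + 0.5))
  }
  omegas <- if (p > 1L) cumsum(deltas) else integer(0)

  if (p > 1L && n_peaks < max(omegas) + 5L)
    stop("n_peaks too small: need at least ", max(omegas) + 5L,
         " so every component contributes >= 5 template isotopes",
         call. = FALSE)
  if (p > 1L && any(deltas > n_peaks - 1L))
    stop("a component's envelope lies entirely outside the template range",
         call. = FALSE)
  if (p > 1L && any(deltas == 0L))
    warning("zero integer mass shift between components ",
            "(near-collinear templates); the fit relies on envelope shape ",
            "differences only", call. = FALSE)

  nt <- as.integer(n_peaks)
  mw <- matrix(0, nt, p)
  dd <- matrix(0, nt, p)
  for (i in seq_len(p)) {
    b <- brain_distribution(comps[[i]], nt)
    mw[, i] <- b$masses
    dd[, i] <- b$abundances
  }
  mz <- if (polarity == "negative") {
    (mw - charge * .mass_proton) / charge
  } else {
    (mw + charge * .mass_proton) / charge
  }

  structure(list(
    components = labels,
    compositions = comps,
    mw_theor = mw,
    d_theor = dd,
    mz_theor = mz,
    n_peaks = nt,
    charge = charge,
    polarity = polarity,
    deltas = deltas,
    omegas = omegas
  ), class = "isotope_pattern_set")
}

#' @export
print.isotope_pattern_set <- function(x, ...) {
  cat("<isotope_pattern_set> ", length(x$components), " component(s), ",
      x$n_peaks, " isotopes, z=", x$charge, " (", x$polarity, ")\n", sep = "")
  for (i in seq_along(x$components)) {
    cat(sprintf("  %-12s mono %.4f Da  (m/z %.4f)\n", x$components[i],
                x$mw_theor[1, i], x$mz_theor[1, i]))
  }
  if (length(x$deltas))
    cat("  integer shifts:", paste(x$deltas, collapse = ", "),
        " cumulative:", paste(x$omegas, collapse = ", "), "\n")
  invisible(x)
}
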