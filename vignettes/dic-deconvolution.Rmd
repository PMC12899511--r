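---
title: "Deconvoluted ion chromatograms: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvoluted ion chromatograms: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dicquant)
```

## The quantification problem

LC-MS1 relative quantification by extracted ion chromatograms assumes
that the signal inside the chosen m/z range belongs to a single species.
For heavy biomolecules whose variants differ by a few Da — deamination
(+1), oxydefluorination (−2), n±x synthesis variants — the isotope
envelopes interleave at ordinary resolving power and the species also
co-elute, so XIC areas double-count the shared region and even an absent
species shows a convincing peak. `dicquant` replaces range integration
with a per-scan mixture model over theoretical isotope templates, turning
one convolved chromatographic peak into one deconvoluted profile (DIC)
per known component.

## Model

### Templates

Each expected component is given as an elemental composition (optionally
a base composition plus add/subtract modifications, e.g. FLP − HF + H2O
for the −2 Da oxydefluorination impurity). Its aggregated isotope
distribution — variants grouped by neutron count, not fine structure —
is computed by a Newton–Girard polynomial recurrence on the elemental
generating polynomials (the BRAIN family of algorithms): occupation
probabilities from the coefficient recurrence, centre masses from the
mass-moment power series. The isotope masses and abundances are embedded
constants (IUPAC/CIAAW 2021 abundances, AME2020 masses, elements C, H,
N, O, P, S, F, Na, Cl, K, Br, I), so results do not drift with external
library versions.

Components are sorted by monoisotopic mass. The differences between
consecutive monoisotopic masses, rounded half away from zero to integers
Δ₁…Δ₍p₋₁₎ with cumulative sums ω, express each heavier envelope as a row
shift on the lightest component's isotope grid. m/z conversion uses the
ESI proton-transfer convention `(M − z·m_p)/z` (negative mode) or
`(M + z·m_p)/z` (positive), with the proton mass 1.00727646688 Da. The
charge carrier is a design choice documented here because the convention
(proton vs hydrogen-atom mass) differs by the electron mass per charge;
proton transfer is the standard reading for ESI of nucleic acids.

### Per-scan fit

For each scan, centroids are matched to the nt mutually exclusive
windows centred on the lightest component's theoretical m/z grid with
relative half-width δ·10⁻⁶ (δ in ppm). Only this one grid is matched:
heavier components are reached through their ω row shifts, and the small
mismatch between an integer-Da shift and the true ~1.003 Da/neutron
spacing must be absorbed by δ (at z = 9 and Δ = 2 the worst-case offset
is ≈ 1.7 ppm, comfortably inside the 10 ppm default). The most intense
centroid per window is kept — ties go to the peak closest to the window
centre, then to the lower m/z, so matching is deterministic — and empty
windows are dropped together with their template row. Matched
intensities give the scan TIC `S_j` and the sum-to-one envelope `O_j`.

The model matrix T places each component's template abundances with its
ω offset on the matched rows and renormalises every column to sum one;
the fit solves

  O_j = Σᵢ Tᵢ e^{θᵢ} + ε_j,  θ̂ = argmin εᵀε,

by Levenberg–Marquardt, initialised at θᵢ = ln(1/p) (equal
contributions). The exponential reparametrisation encodes strict
positivity without constraints; absence of a component is the limit
θ → −∞. Because the model is linear in cᵢ = e^{θᵢ} with cᵢ ≥ 0, the
optimum must coincide with the non-negative least squares solution on
(T, O_j); the test suite exploits this as an independent oracle
(`pracma::lsqnonneg`) on both interior and boundary solutions. The RSS
is unweighted — no Poisson or variance weighting — keeping the estimator
exactly the stated least-squares functional.

### DICs and summaries

Component i's DIC is the point set `(r_j, S_j·e^{θ̂ᵢⱼ})`; every scan
contributes a point, with skipped scans contributing height 0 so the rt
grid stays complete for trapezoid integration. Proportions are
normalised areas `p̂ᵢ = AUCᵢ/Σ AUC`, integrated over the full retention
range by default (restrict with `restrict_rt()` for peak-focused
quantification; window choice is a user decision, not a hidden default).
The residual trace `S_j − Σᵢ S_j e^{θ̂ᵢⱼ}` equals, scan by scan and by
construction, the matched TIC minus the sum of DIC heights; a
systematically positive trace indicates species missing from the model.
No smoothing is applied before integration; a low-pass filter hook was
considered and deliberately left out so that areas remain a pure
function of the fitted coefficients.

## Parameters that matter

| parameter | default | units | notes |
|---|---|---|---|
| `n_peaks` (nt) | 20 | isotope variants | must cover the heaviest component's envelope after its ω shift; enforced: nt ≥ ω₍p₋₁₎ + 5 so every component keeps ≥ 5 template rows. 20 suits 5–10 kDa species. |
| `ppm` (δ) | 10 | ppm | window half-width is multiplicative, `centre·δ·10⁻⁶`. Mutual exclusivity is checked before any matching; violation reports the largest admissible δ for the geometry. Must exceed instrument jitter plus the integer-shift mismatch above. |
| `charge` (z) | — | — | single charge state per analysis; pick the most abundant one. Joint multi-charge fitting is out of scope. |
| `fit_options()` | 200 iter, tol 1e−10 | — | LM step/gradient/RSS tolerances. Tight tolerances cost little (p ≤ 3, n ≤ nt) and pin the NNLS equivalence to < 1e−6. |
| `min_points_over_params` | 1 | peaks | a scan is fitted only when n ≥ p + 1; thinner envelopes are recorded as `skipped_underdetermined`. |

Degenerate inputs are handled by policy, not error: an empty envelope is
`skipped_empty`; a scan on which some component's entire shifted
template falls outside the matched rows is `skipped_underdetermined`
(the component is unobservable there); LM non-convergence keeps the last
iterate with status `not_converged`. All skipped scans still appear in
the DICs (height 0) and in the per-scan CSV. Δ = 0 between two
components (isobaric after rounding) is accepted with a warning — the
fit then relies on envelope-shape differences only and the design is
near-collinear.

## What the simulator does and does not emulate

`simulate_run()` generates: Gaussian elution per component (centre, σ,
relative amount); centroids at the *true* aggregated-variant m/z of each
component at the chosen charge state — deliberately not the integer-Da
approximation, so the alignment faces the same template mismatch real
data does; instrument-style merging of centroids closer than
`merge_ppm` (default 10) into one intensity-weighted peak, as a
centroiding algorithm would output for unresolved neighbours;
multiplicative m/z jitter (ppm-scale); Gaussian (CV-scaled) or Poisson
intensity noise. Each component's truncated envelope (30 variants by
default) is renormalised to sum one, so `amount` is exactly the
component's share of generated ion current and the returned ground
truth is an exact bookkeeping of generated intensities.

Defaults mirror a routine oligonucleotide QC acquisition: 1 Hz MS1
scans over a 2 min window (121 scans), negative-mode ESI, components
~6.5 kDa at z = 9 eluting 0.15 min apart — the co-elution "bump"
scenario in which an impurity shoulders the main product.

It does **not** emulate: ionisation suppression or detector saturation
(the dominant sources of the calibration non-linearity seen on real
instruments), peak tailing (EMG), baseline chemical noise, or profile
peak shapes. Consequently, passing recovery tests here demonstrates
correctness of the deconvolution arithmetic under the model's
assumptions — not robustness to MS response non-linearity, which is a
data property that no per-scan mixture model corrects.

## Numerical and design notes

- **ppm windows, not absolute:** the interval `[b−δ, b+δ]` with δ "in
  ppm" is read multiplicatively, `b·(1 ± δ·10⁻⁶)`; subtracting a ppm
  value from an m/z literally would be dimensionally inconsistent.
- **Δ rounding:** half away from zero on the monoisotopic difference;
  real compositions never land on ties.
- **Unoccupied variants:** a molecule like pure Cl₂ has zero-probability
  neutron counts; their undefined centre masses are filled with
  `mono + j·1.00335` placeholders to keep the mass grid monotone. For
  CHNOPS(+F) species every variant is occupied and the placeholder never
  triggers.
- **Coefficient floor:** coefficients are reported exactly as estimated;
  tiny values (θ very negative) are the model's representation of
  absence and are not clamped.
- **Naive baseline:** `naive_monoisotopic_estimate()` implements the
  two-isotope hand calculation (component 1 from the uncontaminated
  monoisotopic peak, component 2 from isotope ω₁+1 after subtracting
  component 1's predicted contribution, TIC-weighted across scans). It
  is shipped as a labelled approximation for comparison; its exact
  historical formulation varies between labs and the overlap-corrected
  ratio here is this package's documented choice.
- **Determinism:** there is no randomness in the pipeline (fixed LM
  initialisation); identical inputs give bitwise-identical estimates.
  The simulator consumes its own seed and restores the caller's RNG
  state.

## Problem sizes in the shipped tests

The test and acceptance suites run two-component ~6.5 kDa mixtures at
z = 9 over 121-scan runs (1 Hz, 2 min), 20-template fits, a 7-point
proportion grid spanning 1–99%, 20 replicate noisy runs at CV 5%, and
~100-instance randomised NNLS-equivalence sweeps — a few seconds on one
CPU in total. These sizes were chosen as the smallest that exercise
every regime (trace-level impurity, balanced mixture, pure sample,
boundary NNLS solutions); all thresholds asserted in the tests are
stated in the tests themselves.

## Known limitations

- One charge state at a time; evidence across charge states is not
  pooled.
- Components must be declared a priori (targeted method); unknown
  species only manifest in the residual trace.
- Quantification is relative ion current, not concentration: response
  factors, suppression and saturation are properties of the data.
- The leftmost-grid alignment assumes the lightest component's grid
  spans all envelopes; nt must be generous (hence the guard and the
  large default).
- Fine isotope structure is out of scope by construction (aggregated
  variants only), as is profile-mode peak picking.
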