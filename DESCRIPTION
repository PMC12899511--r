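Package: dicquant
Title: Deconvoluted Ion Chromatograms for Quantifying Co-Eluting
    Isotope-Overlapping Species in LC-MS1 Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Relative quantification of known mixture components whose
    isotope envelopes overlap both chromatographically and in m/z, from
    centroided LC-MS1 data. Aggregated theoretical isotope distributions
    are computed from elemental compositions with a polynomial-recurrence
    (BRAIN-type) algorithm, experimental peaks are aligned to ppm windows
    around the lightest component's isotope grid, and each mass scan is
    modelled as a non-negative linear combination of shifted theoretical
    templates fitted by exponentially reparametrised least squares. The
    per-scan coefficients yield deconvoluted extracted ion chromatograms
    (DICs) whose trapezoid areas give mixture proportions, e.g. of a
    full-length oligonucleotide product and its small-Da-shift impurities.
    Includes an mzML reader/writer and a ground-truth LC-MS1 simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    mzR,
    pracma,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
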