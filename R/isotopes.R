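#' @keywords internal
"_PACKAGE"

# Embedded stable-isotope table (IUPAC CIAAW 2021 representative abundances;
# atomic masses from AME2020). Fixed constants so results do not depend on
# any external library's table version.
.isotope_table <- list(
  H  = list(mass = c(1.00782503207, 2.01410177785),
            abundance = c(0.999885, 0.000115)),
  C  = list(mass = c(12.0, 13.00335483507),
            abundance = c(0.9893, 0.0107)),
  N  = list(mass = c(14.00307400443, 15.00010889888),
            abundance = c(0.99636, 0.00364)),
  O  = list(mass = c(15.99491461957, 16.99913175650, 17.99915961286),
            abundance = c(0.99757, 0.00038, 0.00205)),
  P  = list(mass = 30.97376199842, abundance = 1),
  S  = list(mass = c(31.9720711744, 32.9714589098, 33.967867004, 35.96708071),
            abundance = c(0.9499, 0.0075, 0.0425, 0.0001)),
  F  = list(mass = 18.99840316273, abundance = 1),
  Na = list(mass = 22.9897692820, abundance = 1),
  Cl = list(mass = c(34.968852682, 36.965902602),
            abundance = c(0.7576, 0.2424)),
  K  = list(mass = c(38.9637064864, 39.963998166, 40.9618252579),
            abundance = c(0.932581, 0.000117, 0.067302)),
  Br = list(mass = c(78.9183376, 80.9162897),
            abundance = c(0.5069, 0.4931)),
  I  = list(mass = 126.9044719, abundance = 1)
)

# Proton mass in Da; the ESI charge carrier for [M - zH]^z- / [M + zH]^z+.
.mass_proton <- 1.00727646688

#' Supported chemical elements
#'
#' Element symbols available in the built-in isotope table.
#'
#' @return Character vector of element symbols.
#' @export
supported_elements <- function() names(.isotope_table)

#' Monoisotopic mass of an elemental composition
#'
#' Sum over elements of atom count times the mass of the lightest stable
#' isotope.
#'
#' @param comp An `elemental_composition` (see [parse_composition()]).
#' @return Monoisotopic mass in Da.
#' @examples
#' monoisotopic_mass(parse_composition("H2O"))
#' @export
monoisotopic_mass <- function(comp) {
  comp <- as_composition(comp)
  sum(vapply(names(comp$counts), function(el) {
    comp$counts[[el]] * .isotope_table[[el]]$mass[1]
  }, numeric(1)))
}
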