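#' Parse a molecular formula string
#'
#' Parses formulas of the form `"C203H255N77O118P19S4F9"` into an
#' `elemental_composition`. An omitted count means one atom (`"P"` is one
#' phosphorus). Only elements present in the built-in isotope table are
#' accepted; see [supported_elements()].
#'
#' @param text Formula string, e.g. `"H2O"`.
#' @return An object of class `elemental_composition`: a named list with a
#'   `counts` element mapping element symbol to atom count.
#' @examples
#' parse_composition("C10H12N5O6P")
#' @export
parse_composition <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text))
    stop("empty formula string", call. = FALSE)
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", text))
    stop("malformed formula: '", text, "'", call. = FALSE)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  counts <- list()
  for (tok in toks) {
    el <- sub("[0-9]*$", "", tok)
    nstr <- sub("^[A-Za-z]+", "", tok)
    n <- if (nzchar(nstr)) as.integer(nstr) else 1L
    if (!el %in% names(.isotope_table))
      stop("unknown element symbol: '", el, "'", call. = FALSE)
    counts[[el]] <- (counts[[el]] %||% 0L) + n
  }
  new_composition(counts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_composition <- function(counts) {
  # Hill order: C, H, then remaining elements alphabetically
  els <- names(counts)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  counts <- counts[hill]
  counts <- counts[vapply(counts, function(x) x > 0, logical(1))]
  if (length(counts) == 0L)
    stop("composition has no atoms", call. = FALSE)
  structure(list(counts = counts), class = "elemental_composition")
}

as_composition <- function(x) {
  if (inherits(x, "elemental_composition")) return(x)
  if (is.character(x)) return(parse_composition(x))
  stop("cannot interpret object of class '", class(x)[1],
       "' as an elemental composition", call. = FALSE)
}

#' Canonical formula string of a composition
#'
#' Elements appear in the fixed order of the built-in isotope table; counts
#' of one are omitted. `parse_composition(format(x))` round-trips.
#'
#' @param x An `elemental_composition`.
#' @param ... Ignored.
#' @export
format.elemental_composition <- function(x, ...) {
  paste0(vapply(names(x$counts), function(el) {
    n <- x$counts[[el]]
    if (n == 1L) el else paste0(el, n)
  }, character(1)), collapse = "")
}

#' @export
print.elemental_composition <- function(x, ...) {
  cat("<elemental_composition> ", format(x),
      "  (monoisotopic ", sprintf("%.5f", monoisotopic_mass(x)), " Da)\n",
      sep = "")
  invisible(x)
}

#' Add and subtract compositions
#'
#' Element-wise arithmetic on atom counts, used to express a modified
#' species relative to a base composition — e.g. an oxydefluorination
#' impurity as full-length product minus HF plus H2O (a net -1.9957 Da
#' shift).
#'
#' @param base Base `elemental_composition` (or formula string).
#' @param add List of compositions/formula strings to add.
#' @param subtract List of compositions/formula strings to subtract.
#' @return The resulting `elemental_composition`.
#' @examples
#' composition_arith("CH4", add = list("O"), subtract = list("H2"))
#' @export
composition_arith <- function(base, add = list(), subtract = list()) {
  base <- as_composition(base)
  if (inherits(add, "elemental_composition") || is.character(add))
    add <- list(add)
  if (inherits(subtract, "elemental_composition") || is.character(subtract))
    subtract <- list(subtract)
  counts <- base$counts
  for (a in add) {
    a <- as_composition(a)
    for (el in names(a$counts))
      counts[[el]] <- (counts[[el]] %||% 0L) + a$counts[[el]]
  }
  for (s in subtract) {
    s <- as_composition(s)
    for (el in names(s$counts)) {
      new <- (counts[[el]] %||% 0L) - s$counts[[el]]
      if (new < 0)
        stop("subtraction drives element '", el, "' below zero", call. = FALSE)
      counts[[el]] <- new
    }
  }
  counts <- counts[vapply(counts, function(x) x > 0, logical(1))]
  if (length(counts) == 0L)
    stop("resulting composition has no atoms", call. = FALSE)
  new_composition(counts)
}
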