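# Molecular-formula arithmetic and monoisotopic mass bookkeeping.

# Monoisotopic (lightest-isotope) masses, NIST/CODATA values.
MONOISOTOPIC_MASS <- c(
  C = 12.0,
  H = 1.00782503207,
  N = 14.0030740048,
  O = 15.99491461956,
  P = 30.97376163,
  S = 31.97207100
)

ELECTRON_MASS <- 5.48579909e-4  # Da

#' Parse a Hill-notation molecular formula
#'
#' Converts a formula string such as `"C25H38O6"` into a named integer vector
#' of element counts. An omitted multiplier counts as 1. Only elements with an
#' entry in the embedded monoisotopic mass table (C, H, N, O, P, S) are
#' accepted.
#'
#' @param text Formula string, e.g. `"C25H39O6"` (the protonated rasfonin ion).
#' @return An object of class `molecular_formula`: a named integer vector of
#'   positive element counts.
#' @examples
#' parse_formula("C25H38O6")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("formula must be a single non-empty string")
  m <- gregexpr("[A-Z][a-z]?[0-9]*", text)[[1]]
  tokens <- regmatches(text, gregexpr("[A-Z][a-z]?[0-9]*", text))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text))
    stop("malformed formula string: ", text)
  syms <- sub("[0-9]*$", "", tokens)
  mult <- sub("^[A-Z][a-z]?", "", tokens)
  n <- ifelse(nzchar(mult), suppressWarnings(as.integer(mult)), 1L)
  bad <- setdiff(syms, names(MONOISOTOPIC_MASS))
  if (length(bad)) stop("unknown element symbol(s): ", paste(bad, collapse = ", "))
  if (any(is.na(n)) || any(n <= 0L)) stop("element multipliers must be positive integers")
  counts <- tapply(n, factor(syms, levels = unique(syms)), sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  structure(out, class = "molecular_formula")
}

#' Format a molecular formula in Hill notation
#'
#' Hill order: C first, then H, then all other elements alphabetically
#' (alphabetical throughout if no carbon). `parse_formula(format_formula(x))`
#' recovers `x`.
#'
#' @param formula A `molecular_formula` or named count vector.
#' @return A single formula string.
#' @export
format_formula <- function(formula) {
  counts <- unclass(formula)
  syms <- names(counts)
  if ("C" %in% syms) {
    ord <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  } else {
    ord <- sort(syms)
  }
  counts <- counts[ord]
  paste0(ord, ifelse(counts == 1L, "", counts), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula>", format_formula(x), "\n")
  invisible(x)
}

#' Monoisotopic mass of a formula, with electron correction for ions
#'
#' Sums the lightest-isotope mass of every atom and subtracts `charge`
#' electron masses, so that for a positive ion the value is directly
#' comparable to an observed m/z (for |charge| = 1).
#'
#' @param formula A `molecular_formula`, named count vector, or formula string.
#' @param charge Integer charge state; default 0 (neutral molecule).
#' @return Mass in Da (for |charge| <= 1, equal to m/z).
#' @examples
#' monoisotopic_mass("C25H39O6", charge = 1)  # 435.2741, the [M+H]+ ion
#' @export
monoisotopic_mass <- function(formula, charge = 0L) {
  if (is.character(formula)) formula <- parse_formula(formula)
  counts <- unclass(formula)
  missing_el <- setdiff(names(counts), names(MONOISOTOPIC_MASS))
  if (length(missing_el))
    stop("no monoisotopic mass tabulated for: ", paste(missing_el, collapse = ", "))
  sum(counts * MONOISOTOPIC_MASS[names(counts)]) - charge * ELECTRON_MASS
}
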