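# Monoisotopic masses of the most abundant isotope, Da. 12C defines the scale.
.monoisotopic_masses <- c(
  C  = 12.0,
  H  = 1.00782503,
  N  = 14.00307401,
  O  = 15.99491462,
  S  = 31.97207069,
  P  = 30.97376163,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  B  = 11.0093054,
  Si = 27.97692653,
  Se = 79.9165213,
  Na = 22.98976928,
  K  = 38.96370668
)

#' Parse a molecular formula in Hill notation
#'
#' Accepts a concatenation of element symbols, each followed by an optional
#' positive integer count (absent count means 1), e.g. `"C27H35N4O6S2"` or
#' `"C2H6O"`. Only elements present in the bundled monoisotopic mass table
#' are accepted.
#'
#' @param text A single formula string.
#' @return A `molecular_formula` object: a named integer vector of element
#'   counts, printed and serialized in Hill order (C, H, then alphabetical).
#' @examples
#' parse_formula("C27H35N4O6S2")
#' parse_formula("H")
#' @seealso [monoisotopic_mass()], [format_formula()]
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text))
    stop("formula must be a single character string")
  if (!nzchar(text))
    stop("formula parse error at position 1: empty string")
  counts <- integer(0)
  pos <- 1L
  n <- nchar(text)
  while (pos <= n) {
    rest <- substr(text, pos, n)
    m <- regmatches(rest, regexpr("^[A-Z][a-z]?", rest))
    if (length(m) == 0L)
      stop(sprintf("formula parse error at position %d: expected an element symbol, got '%s'",
                   pos, substr(text, pos, pos)))
    sym <- m
    # prefer the two-letter symbol only if it is a known element
    if (nchar(sym) == 2L && !(sym %in% names(.monoisotopic_masses)))
      sym <- substr(sym, 1L, 1L)
    if (!(sym %in% names(.monoisotopic_masses)))
      stop(sprintf("formula parse error at position %d: unknown element '%s'", pos, m))
    pos <- pos + nchar(sym)
    rest <- substr(text, pos, n)
    d <- regmatches(rest, regexpr("^[0-9]+", rest))
    if (length(d) == 0L) {
      cnt <- 1L
    } else {
      cnt <- suppressWarnings(as.integer(d))
      if (is.na(cnt) || cnt == 0L)
        stop(sprintf("formula parse error at position %d: count must be a positive integer", pos))
      pos <- pos + nchar(d)
    }
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + cnt else cnt
  }
  new_molecular_formula(counts)
}

new_molecular_formula <- function(counts) {
  counts <- counts[hill_order(names(counts))]
  storage.mode(counts) <- "integer"
  structure(counts, class = "molecular_formula")
}

hill_order <- function(symbols) {
  first <- intersect(c("C", "H"), symbols)
  c(first, sort(setdiff(symbols, first)))
}

#' Serialize a molecular formula to Hill notation
#'
#' @param f A `molecular_formula` (or named count vector).
#' @return The Hill-notation string; counts of 1 are omitted.
#' @export
format_formula <- function(f) {
  syms <- hill_order(names(f))
  paste0(vapply(syms, function(s) {
    if (f[[s]] == 1L) s else paste0(s, f[[s]])
  }, character(1)), collapse = "")
}

#' @export
print.molecular_formula <- function(x, ...) {
  cat("<molecular_formula>", format_formula(x), "\n")
  invisible(x)
}

#' @export
`+.molecular_formula` <- function(e1, e2) {
  syms <- union(names(e1), names(e2))
  out <- vapply(syms, function(s) {
    (if (s %in% names(e1)) e1[[s]] else 0L) + (if (s %in% names(e2)) e2[[s]] else 0L)
  }, integer(1))
  new_molecular_formula(out)
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums neutral-atom monoisotopic masses (most abundant isotope of each
#' element; the electron mass is ignored). For a formula printed as the
#' protonated species, as in HRMS "\[M+H\]+ calcd" lines, this reproduces
#' the printed calcd value.
#'
#' @param f A `molecular_formula` or a formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C27H35N4O6S2") # 575.1998
#' @export
monoisotopic_mass <- function(f) {
  if (is.character(f)) f <- parse_formula(f)
  missing <- setdiff(names(f), names(.monoisotopic_masses))
  if (length(missing))
    stop("no monoisotopic mass tabulated for element(s): ",
         paste(missing, collapse = ", "))
  sum(unclass(f) * .monoisotopic_masses[names(f)])
}

#' Convert IC50 in nM to pIC50
#'
#' pIC50 = -log10(IC50 in mol/L). 1000 nM (1 uM) gives 6.0.
#'
#' @param ic50_nM Positive IC50 value(s) in nanomolar.
#' @return pIC50 value(s), dimensionless.
#' @export
pic50 <- function(ic50_nM) {
  if (!is.numeric(ic50_nM) || any(is.na(ic50_nM)) || any(ic50_nM <= 0))
    stop("ic50_nM must be positive")
  -log10(ic50_nM * 1e-9)
}

#' Convert pIC50 back to IC50 in nM
#'
#' Inverse of [pic50()]: IC50(nM) = 10^(9 - pIC50).
#'
#' @param p pIC50 value(s).
#' @return IC50 in nanomolar.
#' @export
ic50_nM <- function(p) 10^(9 - p)

#' Fold-potency ratio
#'
#' Ratio of two IC50s rounded to the nearest integer, half away from zero —
#' the conventional reading of "n-fold higher".
#'
#' @param a_nM,b_nM Positive concentrations (same units); the result is
#'   `round(a/b)` with ties away from zero.
#' @return Integer fold change.
#' @examples
#' fold_ratio(906, 64)  # 14
#' fold_ratio(2950, 64) # 46
#' @export
fold_ratio <- function(a_nM, b_nM) {
  if (!is.numeric(a_nM) || !is.numeric(b_nM) || any(a_nM <= 0))
    stop("concentrations must be positive")
  if (any(b_nM <= 0)) stop("reference concentration must be positive")
  r <- a_nM / b_nM
  as.integer(sign(r) * floor(abs(r) + 0.5))
}
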