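## Atomic mass constants and elemental-formula arithmetic.
##
## All masses in the package derive from this single table so that results
## are bit-stable across platforms.  Monoisotopic masses are the masses of
## the most abundant isotope; average masses are standard atomic weights.

#' Atomic mass tables
#'
#' Named numeric vectors of monoisotopic atomic masses and standard atomic
#' weights (Da) for the elements occurring in nucleic acids.  These are the
#' only mass constants used by the package.
#'
#' @format Named numeric vectors (`H`, `C`, `N`, `O`, `P`, `S`).
#' @name atomic_masses
NULL

#' @rdname atomic_masses
#' @export
ATOMIC_MONO <- c(
  H = 1.007825,
  C = 12.000000,
  N = 14.003074,
  O = 15.994915,
  P = 30.973762,
  S = 31.972071
)

#' @rdname atomic_masses
#' @export
ATOMIC_AVG <- c(
  H = 1.007940,
  C = 12.010700,
  N = 14.006700,
  O = 15.999400,
  P = 30.973762,
  S = 32.065000
)

#' Mass of the proton (Da), used for [M + zH]^z+ m/z calculation.
#' @export
PROTON_MASS <- 1.007276

#' Parse an elemental formula string
#'
#' Formulas are written as element symbols followed by optional signed
#' integer counts, e.g. `"C10H14N5O7P"` or, for composition differences,
#' `"CH2"` or `"O-1"` (the 2'-deoxy difference).  An empty string is the
#' empty formula.
#'
#' @param text formula string.
#' @return Named integer vector of element counts (possibly negative for
#'   difference formulas), with zero-count elements dropped.
#' @examples
#' parse_formula("C10H14N5O7P")
#' parse_formula("O-1")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  if (!nzchar(text)) return(integer(0))
  m <- gregexpr("[A-Z][a-z]?(-?[0-9]+)?", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(text)) {
    stop("malformed formula: '", text, "'", call. = FALSE)
  }
  elems <- sub("(-?[0-9]+)$", "", tokens)
  counts <- suppressWarnings(as.integer(sub("^[A-Za-z]+", "", tokens)))
  counts[is.na(counts)] <- 1L
  unknown <- setdiff(elems, names(ATOMIC_MONO))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- tapply(counts, factor(elems, levels = unique(elems)), sum)
  out <- stats::setNames(as.integer(out), names(out))
  out[out != 0L]
}

#' Combine elemental formulas
#'
#' @param ... named integer vectors as returned by [parse_formula()].
#' @return Named integer vector; element order follows first appearance.
#' @export
formula_sum <- function(...) {
  fs <- list(...)
  all_names <- unique(unlist(lapply(fs, names)))
  out <- stats::setNames(integer(length(all_names)), all_names)
  for (f in fs) if (length(f)) out[names(f)] <- out[names(f)] + f
  out[out != 0L]
}

#' Scale a formula by an integer multiplier
#' @param f named integer vector.
#' @param k integer multiplier (may be negative).
#' @export
formula_multiply <- function(f, k) {
  stopifnot(length(k) == 1L, k == as.integer(k))
  out <- f * as.integer(k)
  out[out != 0L]
}

#' Mass of an elemental formula
#'
#' @param f named integer vector of element counts.
#' @param mass_type `"mono"` (monoisotopic, default) or `"avg"`.
#' @return Mass in Da (0 for the empty formula).
#' @export
formula_mass <- function(f, mass_type = c("mono", "avg")) {
  mass_type <- match.arg(mass_type)
  if (!length(f)) return(0)
  tab <- if (mass_type == "mono") ATOMIC_MONO else ATOMIC_AVG
  unknown <- setdiff(names(f), names(tab))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(tab[names(f)] * f)
}

#' Format a formula as a canonical string (Hill-like: C, H, then alphabetical)
#' @param f named integer vector.
#' @export
format_formula <- function(f) {
  if (!length(f)) return("")
  ord <- c(intersect(c("C", "H"), names(f)),
           sort(setdiff(names(f), c("C", "H"))))
  f <- f[ord]
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

# Frequently used building blocks.
FORMULA_H2O <- c(H = 2L, O = 1L)
FORMULA_HPO3 <- c(H = 1L, P = 1L, O = 3L)
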