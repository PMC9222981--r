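## Oligonucleotide specification: sequence parsing, elemental composition,
## neutral mass and m/z.

#' Construct an oligonucleotide specification
#'
#' An `oligo_spec` holds an ordered 5'-to-3' token list (residues and
#' bracketed modifications), the strand type, the 5' and 3' end
#' chemistries, and an optional fixed neutral-mass offset modelling a
#' covalent tag (such as the imidazolium ion tag of an ITO probe).
#'
#' @param tokens character vector of residue / modification tokens, 5'->3'.
#' @param strand `"RNA"` or `"DNA"`.
#' @param end5,end3 `"OH"` or `"phosphate"`.
#' @param tag_mass_delta non-negative neutral-mass offset in Da (default 0).
#' @return Object of class `oligo_spec`.
#' @seealso [parse_sequence()] for the string form.
#' @export
oligo_spec <- function(tokens, strand = c("RNA", "DNA"),
                       end5 = c("OH", "phosphate"),
                       end3 = c("OH", "phosphate"),
                       tag_mass_delta = 0) {
  strand <- match.arg(strand)
  end5 <- match.arg(end5)
  end3 <- match.arg(end3)
  stopifnot(is.character(tokens), length(tokens) >= 1L,
            is.numeric(tag_mass_delta), length(tag_mass_delta) == 1L,
            tag_mass_delta >= 0)
  for (i in seq_along(tokens)) {
    if (is.null(.resolve_token(tokens[i], strand))) {
      stop("unknown token '", tokens[i], "' at position ", i,
           " (", strand, ")", call. = FALSE)
    }
  }
  structure(
    list(tokens = tokens, strand = strand, end5 = end5, end3 = end3,
         tag_mass_delta = tag_mass_delta),
    class = "oligo_spec"
  )
}

#' Parse a bracketed oligonucleotide sequence
#'
#' Sequences are written 5'->3' with uppercase residue letters and
#' modification codes in square brackets, e.g. `"GG[m6A]CU"` for a GGACU
#' consensus motif methylated at its adenosine.
#'
#' @param text sequence string.
#' @inheritParams oligo_spec
#' @return An [oligo_spec()].  `parse_sequence(format(x))` reproduces the
#'   token list of `x`.
#' @examples
#' parse_sequence("GG[m6A]CU")
#' parse_sequence("AGTCC", strand = "DNA")
#' @export
parse_sequence <- function(text, strand = c("RNA", "DNA"),
                           end5 = c("OH", "phosphate"),
                           end3 = c("OH", "phosphate"),
                           tag_mass_delta = 0) {
  strand <- match.arg(strand)
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  tokens <- character(0)
  i <- 1L            # character cursor
  pos <- 0L          # 1-based token position, for error messages
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    pos <- pos + 1L
    if (ch == "[") {
      close <- regexpr("]", substr(text, i, n), fixed = TRUE)
      if (close < 0) {
        stop("unterminated '[' at position ", pos, " in '", text, "'",
             call. = FALSE)
      }
      token <- substr(text, i + 1L, i + close - 2L)
      i <- i + close
    } else {
      token <- ch
      i <- i + 1L
    }
    if (is.null(.resolve_token(token, strand))) {
      stop("unknown token '", token, "' at position ", pos, " in '", text,
           "'", call. = FALSE)
    }
    tokens <- c(tokens, token)
  }
  oligo_spec(tokens, strand = strand, end5 = end5, end3 = end3,
             tag_mass_delta = tag_mass_delta)
}

#' @export
format.oligo_spec <- function(x, ...) {
  paste0(ifelse(nchar(x$tokens) > 1L, paste0("[", x$tokens, "]"), x$tokens),
         collapse = "")
}

#' @export
as.character.oligo_spec <- function(x, ...) format(x)

#' @export
print.oligo_spec <- function(x, ...) {
  cat(sprintf("<oligo_spec> %s %s  5'-%s / 3'-%s", x$strand, format(x),
              x$end5, x$end3))
  if (x$tag_mass_delta > 0) cat(sprintf("  +tag %.4f Da", x$tag_mass_delta))
  cat(sprintf("\n  length %d nt, monoisotopic %.4f Da\n",
              length(x$tokens), neutral_mass(x)))
  invisible(x)
}

#' @export
length.oligo_spec <- function(x) length(x$tokens)

#' Elemental composition of an oligonucleotide
#'
#' Sums the internal chain-residue formulas (nucleoside 5'-monophosphate
#' minus water) plus one water, then adjusts the ends: a 5'-OH subtracts
#' HPO3 (the base form carries a 5'-phosphate), a 3'-phosphate adds HPO3.
#' The tag mass offset is *not* part of the composition (it is a pure mass
#' delta; see [neutral_mass()]).
#'
#' @param oligo an [oligo_spec()].
#' @return Named integer vector of element counts.
#' @examples
#' # a single 5'-phosphorylated adenosine is AMP:
#' elemental_composition(parse_sequence("A", end5 = "phosphate"))
#' @export
elemental_composition <- function(oligo) {
  stopifnot(inherits(oligo, "oligo_spec"))
  fs <- lapply(oligo$tokens, function(t) .resolve_token(t, oligo$strand)$formula)
  comp <- do.call(formula_sum, c(fs, list(FORMULA_H2O)))
  if (oligo$end5 == "OH") comp <- formula_sum(comp, formula_multiply(FORMULA_HPO3, -1L))
  if (oligo$end3 == "phosphate") comp <- formula_sum(comp, FORMULA_HPO3)
  comp
}

#' Neutral mass of an oligonucleotide
#'
#' @param oligo an [oligo_spec()].
#' @param mass_type `"mono"` (monoisotopic, default: reflectron MALDI-TOF
#'   resolves isotopes below ~5 kDa) or `"avg"`.
#' @return Neutral mass in Da, including any tag mass offset.
#' @export
neutral_mass <- function(oligo, mass_type = c("mono", "avg")) {
  mass_type <- match.arg(mass_type)
  formula_mass(elemental_composition(oligo), mass_type) + oligo$tag_mass_delta
}

#' m/z of a protonated oligonucleotide ion
#'
#' Positive-mode MALDI produces predominantly singly protonated ions;
#' `m/z = (M + z * m_proton) / z`.
#'
#' @param oligo an [oligo_spec()].
#' @param charge positive integer charge state (default 1).
#' @inheritParams neutral_mass
#' @return m/z value.
#' @export
mz <- function(oligo, charge = 1L, mass_type = c("mono", "avg")) {
  if (!is.numeric(charge) || length(charge) != 1L || charge < 1 ||
      charge != as.integer(charge)) {
    stop("charge must be a positive integer", call. = FALSE)
  }
  (neutral_mass(oligo, mass_type) + charge * PROTON_MASS) / charge
}

# Extract a subsequence [from, to] (1-based, inclusive) as a new oligo_spec
# with explicit end chemistries; tag offsets do not propagate to fragments.
subsequence <- function(oligo, from, to, end5, end3) {
  stopifnot(from >= 1L, to <= length(oligo$tokens), from <= to)
  oligo_spec(oligo$tokens[from:to], strand = oligo$strand,
             end5 = end5, end3 = end3, tag_mass_delta = 0)
}
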