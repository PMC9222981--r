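## Residue and modification registries.
##
## Internal chain residues are nucleoside 5'-monophosphates minus water, so
## that the sum of residue formulas plus one water equals the
## 5'-phosphate / 3'-OH oligonucleotide.  End-chemistry adjustments
## (subtract HPO3 for a 5'-OH, add HPO3 for a 3'-phosphate) are applied on
## top of that base form.

.registry <- new.env(parent = emptyenv())

.residue_table <- function() {
  mk <- function(strand, symbol, formula) {
    f <- parse_formula(formula)
    list(strand = strand, symbol = symbol, formula = f,
         mono_mass = formula_mass(f, "mono"),
         avg_mass = formula_mass(f, "avg"))
  }
  list(
    RNA = list(
      A = mk("RNA", "A", "C10H12N5O6P"),
      C = mk("RNA", "C", "C9H12N3O7P"),
      G = mk("RNA", "G", "C10H12N5O7P"),
      U = mk("RNA", "U", "C9H11N2O8P")
    ),
    DNA = list(
      A = mk("DNA", "A", "C10H12N5O5P"),
      C = mk("DNA", "C", "C9H12N3O6P"),
      G = mk("DNA", "G", "C10H12N5O6P"),
      T = mk("DNA", "T", "C10H13N2O7P")
    )
  )
}

.init_registry <- function() {
  .registry$residues <- .residue_table()
  .registry$modifications <- list()
  register_modification("m6A", parent = "A", delta_formula = "CH2")
  register_modification("m1A", parent = "A", delta_formula = "CH2")
  register_modification("m5C", parent = "C", delta_formula = "CH2")
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  .init_registry()
}

#' Register a residue modification
#'
#' Adds a modification code to the registry used by [parse_sequence()].
#' A modification is defined by the residue it replaces and the elemental
#' difference relative to that residue (e.g. `+CH2` for any single
#' methylation such as N6-methyladenosine).
#'
#' @param code short unique token, used in bracketed sequence notation
#'   (`"GG[m6A]CU"`).
#' @param parent residue symbol the modification replaces (`A`, `C`, `G`,
#'   `U` or `T`).
#' @param delta_formula elemental difference vs. the parent residue, as a
#'   signed formula string (see [parse_formula()]).
#' @param overwrite replace an existing definition of `code`?
#' @return Invisibly, the registered definition (list with `code`,
#'   `parent`, `delta_formula`, `delta_mono`, `delta_avg`).
#' @examples
#' register_modification("hm5C", parent = "C", delta_formula = "CH2O",
#'                       overwrite = TRUE)
#' @export
register_modification <- function(code, parent, delta_formula,
                                  overwrite = FALSE) {
  stopifnot(is.character(code), length(code) == 1L, nzchar(code))
  if (grepl("[][]", code)) stop("modification code may not contain brackets")
  if (!overwrite && code %in% names(.registry$modifications)) {
    stop("modification '", code, "' already registered", call. = FALSE)
  }
  if (!parent %in% c("A", "C", "G", "U", "T")) {
    stop("unknown parent residue: '", parent, "'", call. = FALSE)
  }
  f <- parse_formula(delta_formula)
  def <- list(code = code, parent = parent, delta_formula = f,
              delta_mono = formula_mass(f, "mono"),
              delta_avg = formula_mass(f, "avg"))
  .registry$modifications[[code]] <- def
  invisible(def)
}

#' List registered modifications
#' @return data.frame with columns code, parent, delta_formula, delta_mono,
#'   delta_avg.
#' @export
list_modifications <- function() {
  mods <- .registry$modifications
  data.frame(
    code = vapply(mods, `[[`, "", "code"),
    parent = vapply(mods, `[[`, "", "parent"),
    delta_formula = vapply(mods, function(m) format_formula(m$delta_formula), ""),
    delta_mono = vapply(mods, `[[`, 0, "delta_mono"),
    delta_avg = vapply(mods, `[[`, 0, "delta_avg"),
    row.names = NULL
  )
}

#' Load user modifications from a registry file
#'
#' The registry file is a CSV with header `code,parent,delta_formula`, one
#' modification per row, e.g. `m6A,A,CH2`.
#'
#' @param path path to the CSV file.
#' @param overwrite replace existing codes?
#' @return Invisibly, the number of modifications registered.
#' @export
load_modification_registry <- function(path, overwrite = FALSE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("code", "parent", "delta_formula")
  if (!all(need %in% names(df))) {
    stop("registry file must have columns: ", paste(need, collapse = ", "))
  }
  for (i in seq_len(nrow(df))) {
    register_modification(df$code[i], df$parent[i], df$delta_formula[i],
                          overwrite = overwrite)
  }
  invisible(nrow(df))
}

# Resolve a token to its residue definition (+ modification delta applied).
# Returns list(formula, is_mod, code).
.resolve_token <- function(token, strand) {
  res <- .registry$residues[[strand]]
  if (token %in% names(res)) {
    return(list(formula = res[[token]]$formula, is_mod = FALSE, code = token))
  }
  mod <- .registry$modifications[[token]]
  if (!is.null(mod) && mod$parent %in% names(res)) {
    return(list(
      formula = formula_sum(res[[mod$parent]]$formula, mod$delta_formula),
      is_mod = TRUE, code = token
    ))
  }
  NULL
}
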