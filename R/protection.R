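## Nuclease-protection model: enumerate the theoretical species expected
## after single-strand-specific digestion of a probe-protected RNA.
##
## The probe (an ion-tagged DNA oligonucleotide) hybridizes to a short
## motif window of the full-length RNA; everything single-stranded is
## degraded.  The observable species are the liberated intact motif target,
## degradation fragments of the motif window (from imperfect protection),
## and the probe itself.

#' Describe a nuclease-protection assay
#'
#' @param full_rna [oligo_spec()] of the full-length RNA standard (e.g. a
#'   15-mer carrying the consensus motif).
#' @param motif_start,motif_end 1-based inclusive coordinates of the
#'   probe-protected window on `full_rna`.
#' @param probe [oligo_spec()] of the complementary DNA probe; its length
#'   must equal the window length.  Model an ion tag via the probe's
#'   `tag_mass_delta`.
#' @param nuclease_end5,nuclease_end3 end chemistry left by the nuclease at
#'   cleavage-created termini.  Mung bean nuclease leaves 5'-phosphate /
#'   3'-OH products (the defaults).
#' @param probe_target_ratio,digest_temp_C,digest_units assay metadata,
#'   recorded but not used in mass prediction (defaults: 2:1 probe:target,
#'   15 degrees C, 5 units).
#' @return Object of class `protection_assay`.
#' @export
protection_assay <- function(full_rna, motif_start, motif_end, probe,
                             nuclease_end5 = "phosphate",
                             nuclease_end3 = "OH",
                             probe_target_ratio = 2,
                             digest_temp_C = 15,
                             digest_units = 5) {
  stopifnot(inherits(full_rna, "oligo_spec"), inherits(probe, "oligo_spec"))
  n <- length(full_rna$tokens)
  if (!(motif_start >= 1 && motif_start <= motif_end && motif_end <= n)) {
    stop("motif window [", motif_start, ", ", motif_end,
         "] must lie within 1..", n, call. = FALSE)
  }
  if (length(probe$tokens) != motif_end - motif_start + 1L) {
    stop("probe length (", length(probe$tokens),
         ") must equal the motif window length (",
         motif_end - motif_start + 1L, ")", call. = FALSE)
  }
  structure(
    list(full_rna = full_rna, motif_start = as.integer(motif_start),
         motif_end = as.integer(motif_end), probe = probe,
         nuclease_end5 = match.arg(nuclease_end5, c("phosphate", "OH")),
         nuclease_end3 = match.arg(nuclease_end3, c("OH", "phosphate")),
         probe_target_ratio = probe_target_ratio,
         digest_temp_C = digest_temp_C, digest_units = digest_units),
    class = "protection_assay"
  )
}

#' @export
print.protection_assay <- function(x, ...) {
  cat(sprintf(
    "<protection_assay> %s\n  motif window %d-%d (%s)\n  probe %s (%s)\n",
    format(x$full_rna), x$motif_start, x$motif_end,
    paste0(x$full_rna$tokens[x$motif_start:x$motif_end], collapse = ""),
    format(x$probe), x$probe$strand))
  cat(sprintf("  nuclease ends 5'-%s / 3'-%s; probe:target %s:1, %g C\n",
              x$nuclease_end5, x$nuclease_end3,
              format(x$probe_target_ratio), x$digest_temp_C))
  invisible(x)
}

# End chemistry of a subsequence [from, to]: termini coinciding with the
# ends of the full molecule keep the original chemistry, cleavage-created
# termini get the nuclease chemistry.
.sub_ends <- function(assay, from, to) {
  n <- length(assay$full_rna$tokens)
  list(
    end5 = if (from == 1L) assay$full_rna$end5 else assay$nuclease_end5,
    end3 = if (to == n) assay$full_rna$end3 else assay$nuclease_end3
  )
}

#' Predict theoretical digestion species
#'
#' Enumerates, for a protection assay: (i) the intact liberated target (the
#' motif window, with nuclease end chemistry at cleavage-created ends and
#' the original end chemistry where the window touches a terminus of the
#' standard); (ii) degradation fragments -- every contiguous proper
#' subsequence of the motif window of length at least `min_frag_len`, with
#' nuclease end chemistry on both ends; (iii) the probe; optionally (iv)
#' the undigested full-length RNA.  Fragments indistinguishable by mass
#' (same base composition and end chemistry) are merged into one species
#' whose `coordinates` field lists all placements.  Species outside the
#' instrument m/z window are dropped.
#'
#' @param assay a [protection_assay()].
#' @param min_frag_len minimum fragment length in nt (default 2;
#'   mononucleotides fall far below the instrument window).
#' @param mass_type `"mono"` or `"avg"`.
#' @param charge charge state for m/z (default 1).
#' @param mz_window numeric `c(low, high)` m/z acceptance window, default
#'   `c(700, 5000)` (reflectron-positive MALDI-TOF acquisition range).
#' @param merge_tol_da fragments within this m/z distance are merged as
#'   isobars (default 0.001 Da; exact isomers coincide to machine
#'   precision).  Set to 0 to disable merging.
#' @param fragment_scope `"motif"` (default) restricts degradation
#'   fragments to the protected window; `"full"` enumerates subsequences of
#'   the whole molecule.
#' @param include_full_length also emit the undigested full-length RNA?
#' @return A `theoretical_species` data.frame, sorted by m/z, with columns
#'   `label` (target/fragment/probe/full_length), `sequence`, `strand`,
#'   `end5`, `end3`, `tag_mass_delta`, `length_nt`, `theoretical_mz`,
#'   `coordinates` (`"start-end"`, `;`-separated for merged isobars, or
#'   `"probe"`).
#' @export
predict_species <- function(assay, min_frag_len = 2L,
                            mass_type = c("mono", "avg"),
                            charge = 1L,
                            mz_window = c(700, 5000),
                            merge_tol_da = 0.001,
                            fragment_scope = c("motif", "full"),
                            include_full_length = FALSE) {
  stopifnot(inherits(assay, "protection_assay"))
  mass_type <- match.arg(mass_type)
  fragment_scope <- match.arg(fragment_scope)
  stopifnot(length(mz_window) == 2L, mz_window[1] < mz_window[2])

  rows <- list()
  add <- function(label, oligo, coords) {
    rows[[length(rows) + 1L]] <<- data.frame(
      label = label, sequence = format(oligo), strand = oligo$strand,
      end5 = oligo$end5, end3 = oligo$end3,
      tag_mass_delta = oligo$tag_mass_delta,
      length_nt = length(oligo$tokens),
      theoretical_mz = mz(oligo, charge = charge, mass_type = mass_type),
      coordinates = coords, stringsAsFactors = FALSE)
  }

  ms <- assay$motif_start; me <- assay$motif_end
  ends <- .sub_ends(assay, ms, me)
  target <- subsequence(assay$full_rna, ms, me, ends$end5, ends$end3)
  add("target", target, paste0(ms, "-", me))

  win_len <- me - ms + 1L
  if (win_len <= min_frag_len && fragment_scope == "motif") {
    warning("motif window (", win_len, " nt) yields no proper fragments of ",
            "length >= ", min_frag_len, call. = FALSE)
  }
  frag_range <- if (fragment_scope == "motif") c(ms, me) else
    c(1L, length(assay$full_rna$tokens))
  span <- frag_range[2] - frag_range[1] + 1L
  for (L in seq_len(span)) {
    if (L < min_frag_len || L >= win_len && fragment_scope == "motif") next
    if (fragment_scope == "full" && L >= length(assay$full_rna$tokens)) next
    for (from in seq(frag_range[1], frag_range[2] - L + 1L)) {
      to <- from + L - 1L
      if (from == ms && to == me) next  # never re-emit the intact target
      frag <- subsequence(assay$full_rna, from, to,
                          assay$nuclease_end5, assay$nuclease_end3)
      add("fragment", frag, paste0(from, "-", to))
    }
  }

  add("probe", assay$probe, "probe")
  if (include_full_length) {
    add("full_length", assay$full_rna,
        paste0(1L, "-", length(assay$full_rna$tokens)))
  }

  tab <- do.call(rbind, rows)

  # merge isobaric fragments (identical label + m/z within tolerance)
  tab <- tab[order(tab$label, tab$theoretical_mz), , drop = FALSE]
  keep <- logical(nrow(tab))
  i <- 1L
  while (i <= nrow(tab)) {
    j <- i
    while (merge_tol_da > 0 && j < nrow(tab) &&
           tab$label[j + 1L] == tab$label[i] &&
           tab$label[i] == "fragment" &&
           abs(tab$theoretical_mz[j + 1L] - tab$theoretical_mz[i]) <= merge_tol_da) {
      j <- j + 1L
    }
    keep[i] <- TRUE
    if (j > i) {
      tab$coordinates[i] <- paste(tab$coordinates[i:j], collapse = ";")
    }
    i <- j + 1L
  }
  tab <- tab[keep, , drop = FALSE]

  tab <- tab[tab$theoretical_mz >= mz_window[1] &
             tab$theoretical_mz <= mz_window[2], , drop = FALSE]
  tab <- tab[order(tab$theoretical_mz), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "mass_type") <- mass_type
  attr(tab, "charge") <- as.integer(charge)
  class(tab) <- c("theoretical_species", "data.frame")
  tab
}

#' Reconstruct the oligo_spec of a species-table row
#' @param species a `theoretical_species` data.frame.
#' @param i row index.
#' @export
species_oligo <- function(species, i) {
  parse_sequence(species$sequence[i], strand = species$strand[i],
                 end5 = species$end5[i], end3 = species$end3[i],
                 tag_mass_delta = species$tag_mass_delta[i])
}

#' Write / read a species table as CSV
#'
#' Deterministic column order; `read_species_csv(write_species_csv(x))`
#' reproduces `x` (m/z to full double precision).
#'
#' @param species a `theoretical_species` data.frame.
#' @param path output path.
#' @export
write_species_csv <- function(species, path) {
  cols <- c("label", "sequence", "strand", "end5", "end3", "tag_mass_delta",
            "length_nt", "theoretical_mz", "coordinates")
  df <- as.data.frame(species)[, cols, drop = FALSE]
  df$theoretical_mz <- sprintf("%.17g", df$theoretical_mz)
  df$tag_mass_delta <- sprintf("%.17g", df$tag_mass_delta)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_species_csv
#' @export
read_species_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  for (cc in c("tag_mass_delta", "theoretical_mz")) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  df$length_nt <- as.integer(df$length_nt)
  class(df) <- c("theoretical_species", "data.frame")
  df
}
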