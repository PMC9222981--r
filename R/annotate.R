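## Peak annotation: assign observed centroid peaks to theoretical species.

#' Match observed peaks to theoretical species
#'
#' Candidate pairs are (species, peak) with absolute mass error within the
#' tolerance.  Assignment is greedy by ascending absolute error, each peak
#' and each species used at most once; ties are broken toward the lower
#' observed m/z.  Because theoretical species are spaced far apart relative
#' to MALDI-TOF mass accuracy, the greedy assignment coincides with the
#' global minimum-total-error assignment in practice.
#'
#' @param pl a [peak_list()].
#' @param species a `theoretical_species` data.frame from
#'   [predict_species()] (nonempty).
#' @param tolerance_da maximum absolute mass error in Da (default 0.5,
#'   appropriate for an externally calibrated MALDI-TOF in the 1.5-5 kDa
#'   range).  Ignored if `tolerance_ppm` is given.
#' @param tolerance_ppm optional relative tolerance in ppm; when supplied,
#'   the per-species tolerance is `tolerance_ppm * theoretical_mz / 1e6`.
#' @param noise a `noise_estimate` from [estimate_noise()], used to attach
#'   SN values to every annotation.
#' @return An `annotation_result`: list with
#'   * `annotations` -- data.frame (label, sequence, coordinates,
#'     theoretical_mz, observed_mz, error_da, error_ppm, intensity, sn),
#'     ordered by theoretical m/z;
#'   * `unmatched_species` -- species rows with no assigned peak;
#'   * `unannotated_peaks` -- peaks with no assigned species;
#'   * `tolerance_da`, `noise`.
#' @export
match_peaks <- function(pl, species, tolerance_da = 0.5,
                        tolerance_ppm = NULL, noise) {
  stopifnot(inherits(pl, "peak_list") || is.data.frame(pl),
            is.data.frame(species), nrow(species) >= 1L,
            inherits(noise, "noise_estimate"))
  if (is.null(tolerance_ppm)) {
    stopifnot(is.numeric(tolerance_da), tolerance_da > 0)
    tol <- rep(tolerance_da, nrow(species))
  } else {
    stopifnot(is.numeric(tolerance_ppm), tolerance_ppm > 0)
    tol <- tolerance_ppm * species$theoretical_mz / 1e6
  }

  np <- nrow(pl)
  cand <- NULL
  if (np > 0L) {
    cand <- do.call(rbind, lapply(seq_len(nrow(species)), function(si) {
      d <- pl$mz - species$theoretical_mz[si]
      hit <- which(abs(d) <= tol[si])
      if (!length(hit)) return(NULL)
      data.frame(species_i = si, peak_i = hit, abs_err = abs(d[hit]),
                 obs_mz = pl$mz[hit])
    }))
  }

  assigned_peak <- integer(0)
  assigned_species <- integer(0)
  picks <- list()
  if (!is.null(cand) && nrow(cand)) {
    cand <- cand[order(cand$abs_err, cand$obs_mz, cand$species_i), ,
                 drop = FALSE]
    for (k in seq_len(nrow(cand))) {
      si <- cand$species_i[k]; pi <- cand$peak_i[k]
      if (si %in% assigned_species || pi %in% assigned_peak) next
      assigned_species <- c(assigned_species, si)
      assigned_peak <- c(assigned_peak, pi)
      picks[[length(picks) + 1L]] <- c(si, pi)
    }
  }

  if (length(picks)) {
    sidx <- vapply(picks, `[`, 0, 1L)
    pidx <- vapply(picks, `[`, 0, 2L)
    ann <- data.frame(
      label = species$label[sidx],
      sequence = species$sequence[sidx],
      coordinates = species$coordinates[sidx],
      theoretical_mz = species$theoretical_mz[sidx],
      observed_mz = pl$mz[pidx],
      intensity = pl$intensity[pidx],
      stringsAsFactors = FALSE)
    ann$error_da <- ann$observed_mz - ann$theoretical_mz
    ann$error_ppm <- 1e6 * ann$error_da / ann$theoretical_mz
    ann$sn <- snr(ann$intensity, noise)
    ann <- ann[order(ann$theoretical_mz), , drop = FALSE]
    rownames(ann) <- NULL
  } else {
    ann <- data.frame(label = character(0), sequence = character(0),
                      coordinates = character(0),
                      theoretical_mz = numeric(0), observed_mz = numeric(0),
                      intensity = numeric(0), error_da = numeric(0),
                      error_ppm = numeric(0), sn = numeric(0))
  }

  unmatched <- species[setdiff(seq_len(nrow(species)), assigned_species), ,
                       drop = FALSE]
  rownames(unmatched) <- NULL
  unann <- as.data.frame(pl)[setdiff(seq_len(np), assigned_peak), ,
                             drop = FALSE]
  rownames(unann) <- NULL

  structure(
    list(annotations = ann, unmatched_species = unmatched,
         unannotated_peaks = unann,
         tolerance_da = if (is.null(tolerance_ppm)) tolerance_da else NA_real_,
         tolerance_ppm = tolerance_ppm, noise = noise),
    class = "annotation_result"
  )
}

#' @export
print.annotation_result <- function(x, ...) {
  cat(sprintf(
    "<annotation_result> %d annotated, %d species unmatched, %d peaks unassigned\n",
    nrow(x$annotations), nrow(x$unmatched_species),
    nrow(x$unannotated_peaks)))
  if (nrow(x$annotations)) {
    print(format(x$annotations[, c("label", "sequence", "theoretical_mz",
                                   "observed_mz", "error_da", "sn")],
                 digits = 6))
  }
  invisible(x)
}

#' Write / read an annotation report CSV
#'
#' Columns: label, sequence, coordinates, theoretical_mz, observed_mz,
#' error_da, error_ppm, intensity, sn; rows ordered by theoretical m/z.
#'
#' @param result an `annotation_result` (or its `annotations` data.frame).
#' @param path output path.
#' @export
write_annotation_csv <- function(result, path) {
  ann <- if (inherits(result, "annotation_result")) result$annotations else result
  cols <- c("label", "sequence", "coordinates", "theoretical_mz",
            "observed_mz", "error_da", "error_ppm", "intensity", "sn")
  df <- ann[, cols, drop = FALSE]
  for (cc in c("theoretical_mz", "observed_mz", "error_da", "error_ppm",
               "intensity", "sn")) {
    df[[cc]] <- sprintf("%.17g", df[[cc]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_annotation_csv
#' @export
read_annotation_csv <- function(path) {
  num <- c("theoretical_mz", "observed_mz", "error_da", "error_ppm",
           "intensity", "sn")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(coordinates = "character"))
  for (cc in num) df[[cc]] <- as.numeric(df[[cc]])
  df
}
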