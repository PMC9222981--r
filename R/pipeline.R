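## End-to-end analysis of stoichiometry datasets: annotate every spectrum,
## extract the modified / unmodified target intensity ratio, and fit the
## calibration line.

#' Analyze a stoichiometry dataset
#'
#' Runs the full measurement pipeline on a set of spectra from a
#' stoichiometry mixture experiment: per spectrum, estimate noise,
#' annotate peaks against the theoretical species table, take the
#' modified:unmodified intact-target intensity ratio, then regress the
#' measured ratios on the nominal mixing ratios.
#'
#' @param ds a `simulated_dataset` from [simulate_stoich_experiment()], or
#'   a list with fields `peak_lists` (named list of [peak_list()]),
#'   `design` (data.frame with `name`, `nominal_ratio`, `replicate`) and
#'   `species` (a `theoretical_species` table containing one modified and
#'   one unmodified target).
#' @param tolerance_da annotation mass tolerance (default 0.5 Da).
#' @param sn_threshold quantification threshold (default 10).
#' @param noise_method noise estimator per spectrum (see
#'   [estimate_noise()]).
#' @param noise_level supplied noise level when
#'   `noise_method = "supplied"`.
#' @param mod_pattern regular expression identifying the modified target
#'   sequence (default matches a bracketed modification token).
#' @param on_fail what to do with spectra whose targets fail the SN
#'   quantification threshold (or cannot be annotated): `"omit"` (default)
#'   excludes them from the calibration, records them in `$failures` and
#'   warns; `"error"` aborts.  A below-threshold target cannot be
#'   quantified, so omission with an audit trail is the standard QC
#'   policy.
#' @return A `stoich_analysis`: list with `ratios` (data.frame: name,
#'   nominal_ratio, replicate, measured_ratio, sn_mod, sn_unmod), `fit`
#'   (a [fit_calibration()] result), `per_ratio` (replicate statistics
#'   of the measured ratio at each nominal ratio) and `failures`
#'   (data.frame: name, reason; zero rows when all spectra pass).
#' @export
analyze_stoich_dataset <- function(ds, tolerance_da = 0.5,
                                   sn_threshold = 10,
                                   noise_method = "mad_low",
                                   noise_level = NULL,
                                   mod_pattern = "\\[",
                                   on_fail = c("omit", "error")) {
  on_fail <- match.arg(on_fail)
  stopifnot(!is.null(ds$peak_lists), !is.null(ds$design),
            !is.null(ds$species))
  species <- ds$species
  tgt <- species[species$label == "target", , drop = FALSE]
  is_mod <- grepl(mod_pattern, tgt$sequence)
  if (sum(is_mod) != 1L || sum(!is_mod) != 1L) {
    stop("species table must contain exactly one modified and one ",
         "unmodified target", call. = FALSE)
  }
  mod_seq <- tgt$sequence[is_mod]
  unmod_seq <- tgt$sequence[!is_mod]

  failures <- list()
  rows <- lapply(seq_len(nrow(ds$design)), function(i) {
    nm <- ds$design$name[i]
    out <- tryCatch({
      pl <- ds$peak_lists[[nm]]
      noise <- estimate_noise(pl, method = noise_method,
                              level = noise_level)
      res <- match_peaks(pl, species, tolerance_da = tolerance_da,
                         noise = noise)
      ann <- res$annotations
      mrow <- ann[ann$label == "target" & ann$sequence == mod_seq, ,
                  drop = FALSE]
      urow <- ann[ann$label == "target" & ann$sequence == unmod_seq, ,
                  drop = FALSE]
      if (nrow(mrow) != 1L || nrow(urow) != 1L) {
        stop("target peak(s) not annotated", call. = FALSE)
      }
      data.frame(name = nm, nominal_ratio = ds$design$nominal_ratio[i],
                 replicate = ds$design$replicate[i],
                 measured_ratio = measured_ratio(mrow, urow,
                                                 sn_threshold = sn_threshold),
                 sn_mod = mrow$sn, sn_unmod = urow$sn,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      if (on_fail == "error") {
        stop("spectrum '", nm, "': ", conditionMessage(e), call. = FALSE)
      }
      failures[[nm]] <<- conditionMessage(e)
      NULL
    })
    out
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(failures)) {
    warning(length(failures), " spectrum/spectra failed quantification QC ",
            "and were omitted: ", paste(names(failures), collapse = ", "),
            call. = FALSE)
  }
  if (!length(rows)) stop("no spectrum passed quantification QC",
                          call. = FALSE)
  ratios <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  fit <- fit_calibration(ratios)
  per_ratio <- do.call(rbind, lapply(split(ratios, ratios$nominal_ratio),
    function(g) {
      st <- replicate_stats(g$measured_ratio)
      data.frame(nominal_ratio = g$nominal_ratio[1], mean = st$mean,
                 sd = st$sd, rsd_percent = st$rsd_percent, n = st$n)
    }))
  rownames(per_ratio) <- NULL

  failures_df <- if (length(failures)) {
    data.frame(name = names(failures), reason = unlist(failures),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(0), reason = character(0))
  }
  structure(list(ratios = ratios, fit = fit, per_ratio = per_ratio,
                 failures = failures_df),
            class = "stoich_analysis")
}

#' @export
print.stoich_analysis <- function(x, ...) {
  cat(sprintf("<stoich_analysis> %d spectra, %d nominal ratios\n",
              nrow(x$ratios), nrow(x$per_ratio)))
  print(x$fit)
  invisible(x)
}

#' Stability ratios for a set of annotated spectra
#'
#' Applies [stability_ratio_from_result()] to each annotation result and
#' summarizes the replicate SRs; with two groups, adds a Welch t-test.
#'
#' @param results named list of `annotation_result` objects (or of
#'   annotation data.frames read back from CSV).
#' @param sn_threshold quantification threshold (default 10).
#' @param target_sequence optional target selector passed through.
#' @param groups optional factor/character vector (same length) for a
#'   two-group comparison.
#' @return List with `per_spectrum` (data.frame: name, sr,
#'   n_fragments_used, target_intensity), `stats` (replicate statistics of
#'   SR) and, when `groups` has two levels, `ttest`.
#' @export
sr_analysis <- function(results, sn_threshold = 10, target_sequence = NULL,
                        groups = NULL) {
  stopifnot(length(results) >= 1L)
  nm <- names(results)
  if (is.null(nm)) nm <- paste0("spectrum", seq_along(results))
  per <- do.call(rbind, lapply(seq_along(results), function(i) {
    x <- results[[i]]
    res <- if (inherits(x, "annotation_result")) {
      stability_ratio_from_result(x, sn_threshold = sn_threshold,
                                  target_sequence = target_sequence)
    } else {
      ann <- x
      tgt <- ann[ann$label == "target", , drop = FALSE]
      if (!is.null(target_sequence)) {
        tgt <- tgt[tgt$sequence == target_sequence, , drop = FALSE]
      }
      if (nrow(tgt) != 1L) {
        stop("annotation table ", nm[i], ": need exactly one target row",
             call. = FALSE)
      }
      stability_ratio(tgt, ann[ann$label == "fragment", , drop = FALSE],
                      sn_threshold = sn_threshold)
    }
    data.frame(name = nm[i], sr = res$sr,
               n_fragments_used = res$n_fragments_used,
               target_intensity = res$target_intensity,
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  out <- list(per_spectrum = per, stats = replicate_stats(per$sr))
  if (!is.null(groups)) {
    g <- as.factor(groups)
    if (nlevels(g) == 2L) {
      out$ttest <- welch_ttest(per$sr[g == levels(g)[1]],
                               per$sr[g == levels(g)[2]])
      out$groups <- levels(g)
    }
  }
  out
}
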