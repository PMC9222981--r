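## Assay metrics: stability ratio, replicate statistics, group comparison,
## stoichiometry ratios, calibration and detection limits.

#' Stability ratio of a protected target
#'
#' The stability ratio summarizes how well the probe protected the motif
#' from nuclease degradation:
#'
#'   SR = 1 - (sum of degradation-fragment intensities) / I_target
#'
#' where only fragments with signal-to-noise at or above `sn_threshold`
#' enter the sum, and the intact-target peak itself must reach the
#' threshold.  SR = 1 means perfect protection (no detectable fragments);
#' SR may go negative when fragments outweigh the target (flagged, not
#' clamped).
#'
#' @param target one annotation row for the intact target (needs columns
#'   `intensity` and `sn`; typically a `label == "target"` row from
#'   [match_peaks()]).
#' @param fragments data.frame of degradation-fragment annotations (same
#'   columns); may be empty or NULL.
#' @param sn_threshold inclusion threshold for both target and fragments
#'   (default 10).
#' @return An `sr_result`: list with `sr`, `n_fragments_used`,
#'   `fragment_sum`, `target_intensity`, `negative` flag.
#' @export
stability_ratio <- function(target, fragments = NULL, sn_threshold = 10) {
  stopifnot(is.data.frame(target), nrow(target) == 1L,
            all(c("intensity", "sn") %in% names(target)))
  if (target$sn < sn_threshold) {
    stop("target below quantification limit (SN = ",
         format(target$sn, digits = 3), " < ", sn_threshold, ")",
         call. = FALSE)
  }
  if (is.null(fragments)) {
    fragments <- data.frame(intensity = numeric(0), sn = numeric(0))
  }
  used <- fragments[fragments$sn >= sn_threshold, , drop = FALSE]
  fragment_sum <- sum(used$intensity)
  sr <- 1 - fragment_sum / target$intensity
  structure(
    list(sr = sr, n_fragments_used = nrow(used), fragment_sum = fragment_sum,
         target_intensity = target$intensity, negative = sr < 0,
         sn_threshold = sn_threshold),
    class = "sr_result"
  )
}

#' @export
print.sr_result <- function(x, ...) {
  cat(sprintf("<sr_result> SR = %.4f (%d fragment%s summed%s)\n", x$sr,
              x$n_fragments_used, if (x$n_fragments_used == 1) "" else "s",
              if (x$negative) "; NEGATIVE: fragments exceed target" else ""))
  invisible(x)
}

#' Stability ratio from an annotation result
#'
#' Convenience wrapper: picks the target and fragment rows out of a
#' [match_peaks()] result and applies [stability_ratio()].  With several
#' target species annotated (e.g. modified and unmodified standards in one
#' spectrum), `target_sequence` selects which one.
#'
#' @param result an `annotation_result`.
#' @param target_sequence optional sequence string selecting the target.
#' @inheritParams stability_ratio
#' @export
stability_ratio_from_result <- function(result, sn_threshold = 10,
                                        target_sequence = NULL) {
  stopifnot(inherits(result, "annotation_result"))
  ann <- result$annotations
  tgt <- ann[ann$label == "target", , drop = FALSE]
  if (!is.null(target_sequence)) {
    tgt <- tgt[tgt$sequence == target_sequence, , drop = FALSE]
  }
  if (nrow(tgt) == 0L) {
    stop("no annotated target peak",
         if (!is.null(target_sequence)) paste0(" for '", target_sequence, "'"),
         call. = FALSE)
  }
  if (nrow(tgt) > 1L) {
    stop("multiple target annotations; disambiguate with target_sequence",
         call. = FALSE)
  }
  frag <- ann[ann$label == "fragment", , drop = FALSE]
  stability_ratio(tgt, frag, sn_threshold = sn_threshold)
}

#' Replicate summary statistics
#'
#' Mean, sample standard deviation (n - 1 denominator) and percent
#' relative standard deviation across replicate measurements.
#'
#' @param values numeric vector, length >= 1.
#' @return List with `mean`, `sd`, `rsd_percent`, `n`.  For a single value
#'   `sd` and `rsd_percent` are `NA`; `rsd_percent` is `NA` when the mean
#'   is not positive.
#' @export
replicate_stats <- function(values) {
  if (!is.numeric(values) || length(values) == 0L || anyNA(values)) {
    stop("values must be a nonempty numeric vector without NA", call. = FALSE)
  }
  n <- length(values)
  m <- mean(values)
  s <- if (n >= 2L) stats::sd(values) else NA_real_
  rsd <- if (!is.na(s) && m > 0) 100 * s / m else NA_real_
  list(mean = m, sd = s, rsd_percent = rsd, n = n)
}

#' Welch two-sample t-test
#'
#' Unpaired t-test with the Welch-Satterthwaite degrees of freedom, as used
#' to compare stability-ratio groups across assay conditions.
#'
#' @param a,b numeric vectors (each n >= 2 with nonzero variance).
#' @return List with `t_stat`, `df`, `p_two_sided`.
#' @export
welch_ttest <- function(a, b) {
  stopifnot(is.numeric(a), is.numeric(b))
  if (length(a) < 2L || length(b) < 2L) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate: both groups have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  list(t_stat = unname(tt$statistic), df = unname(tt$parameter),
       p_two_sided = tt$p.value)
}

#' Measured modified:unmodified stoichiometry ratio
#'
#' The ratio of intact-target peak intensities for the modified and
#' unmodified species in one spectrum.  Because both species co-crystallize
#' in the same MALDI spot, the shared spot factor cancels in the ratio.
#' Both peaks must reach the SN threshold.
#'
#' @param mod,unmod one annotation row each (columns `intensity`, `sn`,
#'   optionally `sequence` for error messages).
#' @param sn_threshold quantification threshold (default 10).
#' @return Numeric ratio `intensity(mod) / intensity(unmod)`.
#' @export
measured_ratio <- function(mod, unmod, sn_threshold = 10) {
  lbl <- function(x, fallback) {
    if (!is.null(x$sequence)) x$sequence[1] else fallback
  }
  for (side in list(list(x = mod, name = "modified"),
                    list(x = unmod, name = "unmodified"))) {
    x <- side$x
    stopifnot(is.data.frame(x), nrow(x) == 1L,
              all(c("intensity", "sn") %in% names(x)))
    if (x$sn < sn_threshold) {
      stop(side$name, " target '", lbl(x, side$name),
           "' below quantification limit (SN = ",
           format(x$sn, digits = 3), " < ", sn_threshold, ")",
           call. = FALSE)
    }
  }
  mod$intensity / unmod$intensity
}

#' Fit a stoichiometry calibration line
#'
#' Ordinary least squares of measured modified:unmodified ratios against
#' the nominal mixing ratios, each replicate entering as its own point.
#'
#' @param samples data.frame with columns `nominal_ratio` and
#'   `measured_ratio` (one row per replicate), or a list of lists with
#'   fields `nominal_ratio` and `measured_ratios`.
#' @param force_origin fit without intercept? (default FALSE: free
#'   intercept).
#' @return A `calibration_fit`: list with `slope`, `intercept`,
#'   `r_squared` (1 - SS_res / SS_tot about the mean response), `residuals`,
#'   `fitted`, `data`, `n`.
#' @export
fit_calibration <- function(samples, force_origin = FALSE) {
  df <- if (is.data.frame(samples)) {
    stopifnot(all(c("nominal_ratio", "measured_ratio") %in% names(samples)))
    samples[, c("nominal_ratio", "measured_ratio")]
  } else {
    do.call(rbind, lapply(samples, function(s) {
      data.frame(nominal_ratio = s$nominal_ratio,
                 measured_ratio = s$measured_ratios)
    }))
  }
  stopifnot(nrow(df) >= 2L, all(df$nominal_ratio > 0),
            all(df$measured_ratio > 0))
  if (length(unique(df$nominal_ratio)) < 2L) {
    stop("need at least 2 distinct nominal ratios", call. = FALSE)
  }
  fit <- if (force_origin) {
    stats::lm(measured_ratio ~ 0 + nominal_ratio, data = df)
  } else {
    stats::lm(measured_ratio ~ nominal_ratio, data = df)
  }
  co <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((df$measured_ratio - mean(df$measured_ratio))^2)
  structure(
    list(slope = unname(co[["nominal_ratio"]]),
         intercept = if (force_origin) 0 else unname(co[["(Intercept)"]]),
         r_squared = 1 - ss_res / ss_tot,
         residuals = unname(stats::residuals(fit)),
         fitted = unname(stats::fitted(fit)),
         data = df, n = nrow(df), force_origin = force_origin),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf(
    "<calibration_fit> measured = %.4f * nominal %s %.4f  (R^2 = %.4f, n = %d)\n",
    x$slope, if (x$intercept < 0) "-" else "+", abs(x$intercept),
    x$r_squared, x$n))
  invisible(x)
}

#' Limits of detection and quantification
#'
#' Converts a blank-spectrum noise level into amount units through the
#' linear response slope: LOD corresponds to a peak at 3x the blank noise,
#' LOQ to SN = 10.  Hence `loq / lod = 10 / 3` whenever both derive from
#' the same noise and slope.
#'
#' @param blank_noise noise level of a blank analysis (intensity units,
#'   > 0); see [estimate_noise()] with `method = "blank"`.
#' @param response_slope linear response in intensity per pmol (> 0).
#' @return List with `lod_amount`, `loq_amount` (pmol), `blank_noise`,
#'   `response_slope`.
#' @export
detection_limits <- function(blank_noise, response_slope) {
  if (inherits(blank_noise, "noise_estimate")) blank_noise <- blank_noise$level
  stopifnot(is.numeric(blank_noise), is.numeric(response_slope))
  if (blank_noise <= 0 || response_slope <= 0) {
    stop("blank_noise and response_slope must be > 0", call. = FALSE)
  }
  list(lod_amount = 3 * blank_noise / response_slope,
       loq_amount = 10 * blank_noise / response_slope,
       blank_noise = blank_noise, response_slope = response_slope)
}
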