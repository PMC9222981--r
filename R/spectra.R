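## Centroid peak lists: I/O, noise estimation, signal-to-noise.

#' Construct a centroid peak list
#'
#' @param mz numeric vector of m/z values (will be sorted; duplicates are
#'   an error).
#' @param intensity non-negative intensities, same length.
#' @param metadata optional named list (polarity, instrument notes, ...).
#' @return A `peak_list`: data.frame with columns `mz`, `intensity`, sorted
#'   by strictly increasing m/z.  A zero-row peak list represents a blank.
#' @export
peak_list <- function(mz = numeric(0), intensity = numeric(0),
                      metadata = list()) {
  stopifnot(is.numeric(mz), is.numeric(intensity),
            length(mz) == length(intensity))
  if (any(is.na(mz)) || any(is.na(intensity))) {
    stop("peak list may not contain NA values", call. = FALSE)
  }
  if (any(intensity < 0)) stop("negative intensity", call. = FALSE)
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) stop("duplicate m/z values", call. = FALSE)
  structure(data.frame(mz = mz, intensity = intensity),
            metadata = metadata,
            class = c("peak_list", "data.frame"))
}

#' @export
print.peak_list <- function(x, ...) {
  cat(sprintf("<peak_list> %d peaks", nrow(x)))
  if (nrow(x)) {
    cat(sprintf(", m/z %.2f-%.2f, max intensity %.3g",
                min(x$mz), max(x$mz), max(x$intensity)))
  }
  cat("\n")
  invisible(x)
}

#' Read a centroid peak list from CSV
#'
#' Expected format: header `mz,intensity`, numeric rows, `.` decimal
#' separator.  Rows are sorted on read.
#'
#' @param path CSV path.
#' @return A [peak_list()]; an empty file body yields an empty peak list
#'   with a warning.
#' @export
read_peaklist_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("mz", "intensity") %in% names(df))) {
    stop("peak-list CSV must have header 'mz,intensity': ", path,
         call. = FALSE)
  }
  if (nrow(df) == 0L) {
    warning("empty peak list: ", path, call. = FALSE)
    return(peak_list())
  }
  peak_list(as.numeric(df$mz), as.numeric(df$intensity))
}

#' Write a peak list to CSV (full double precision round-trip)
#' @param pl a [peak_list()].
#' @param path output path.
#' @export
write_peaklist_csv <- function(pl, path) {
  df <- data.frame(mz = sprintf("%.17g", pl$mz),
                   intensity = sprintf("%.17g", pl$intensity))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the first (or selected) spectrum of an mzML file as a peak list
#'
#' Requires the `mzR` package.  Only centroid-mode spectra are supported.
#'
#' @param path mzML file.
#' @param scan 1-based spectrum index (default 1).
#' @return A [peak_list()].
#' @export
read_mzml <- function(path, scan = 1L) {
  if (!requireNamespace("mzR", quietly = TRUE)) {
    stop("read_mzml requires the 'mzR' package", call. = FALSE)
  }
  h <- mzR::openMSfile(path)
  on.exit(mzR::close(h))
  hdr <- mzR::header(h, scan)
  if (!is.na(hdr$centroided) && !isTRUE(hdr$centroided)) {
    stop("profile-mode spectra are not supported; centroid first",
         call. = FALSE)
  }
  p <- mzR::peaks(h, scan)
  if (NROW(p) == 0L) return(peak_list())
  peak_list(p[, 1], p[, 2])
}

#' Estimate the spectrum noise level
#'
#' The default `mad_low` estimator is robust to a handful of strong analyte
#' peaks: it takes the peaks at or below the median intensity and returns
#' 1.4826 times their median absolute deviation (the scale factor makes the
#' estimator consistent for Gaussian noise).  The `blank` method applies
#' the same statistic to an entire blank spectrum (for detection-limit
#' work); `supplied` passes a user value through.
#'
#' @param pl a [peak_list()] (the analyte spectrum for `mad_low`, a blank
#'   spectrum for `blank`).
#' @param method `"mad_low"`, `"blank"` or `"supplied"`.
#' @param level user-supplied noise level (required for
#'   `method = "supplied"`).
#' @return A `noise_estimate`: list with `level` (> 0), `method`,
#'   `n_peaks_used`.
#' @export
estimate_noise <- function(pl, method = c("mad_low", "blank", "supplied"),
                           level = NULL) {
  method <- match.arg(method)
  if (method == "supplied") {
    stopifnot(is.numeric(level), length(level) == 1L)
    if (level <= 0) stop("supplied noise level must be > 0", call. = FALSE)
    return(structure(list(level = level, method = "supplied",
                          n_peaks_used = 0L), class = "noise_estimate"))
  }
  stopifnot(inherits(pl, "peak_list") || is.data.frame(pl))
  x <- pl$intensity
  if (method == "mad_low") {
    if (length(x) < 5L) {
      stop("mad_low needs >= 5 peaks; use method = 'supplied'",
           call. = FALSE)
    }
    x <- x[x <= stats::median(x)]
  }
  if (length(x) == 0L) {
    stop("no peaks to estimate noise from; use method = 'supplied'",
         call. = FALSE)
  }
  lvl <- 1.4826 * stats::median(abs(x - stats::median(x)))
  if (lvl <= 0) {
    stop("degenerate intensities (MAD = 0); use method = 'supplied'",
         call. = FALSE)
  }
  structure(list(level = lvl, method = method, n_peaks_used = length(x)),
            class = "noise_estimate")
}

#' @export
print.noise_estimate <- function(x, ...) {
  cat(sprintf("<noise_estimate> level %.4g (%s, %d peaks)\n",
              x$level, x$method, x$n_peaks_used))
  invisible(x)
}

#' Signal-to-noise ratio of a peak
#'
#' @param peak_intensity intensity (vectorized).
#' @param noise a `noise_estimate` from [estimate_noise()].
#' @return `peak_intensity / noise$level`.
#' @export
snr <- function(peak_intensity, noise) {
  stopifnot(inherits(noise, "noise_estimate"), noise$level > 0)
  peak_intensity / noise$level
}
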