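## Seeded synthetic-spectrum generator.
##
## Measurement model: each species i with loaded amount a_i (pmol) yields
## a centroid peak of intensity
##
##     I_i = a_i * response_factor * S * E_i
##
## where S is a per-spectrum shared "spot factor" (lognormal, median 1,
## CV = cv_shared) modelling spot-to-spot MALDI variability, and E_i is an
## independent per-species factor (lognormal, median 1, CV = cv_indep).
## The two-tier structure lets single-peak intensities vary at the ~20%
## level while within-spectrum intensity *ratios* stay much tighter -- the
## mechanism that makes ratio-based stoichiometry precise.  Observed m/z
## is the theoretical value plus Gaussian jitter; decoy (noise) peaks are
## uniform in m/z with half-normal intensities.

#' Simulation configuration
#'
#' @param response_factor linear response, intensity units per pmol
#'   (default 10).
#' @param cv_shared coefficient of variation of the shared per-spectrum
#'   spot factor (default 0.20).
#' @param cv_indep per-species independent CV (default 0.05).
#' @param mz_jitter_sd Gaussian m/z jitter SD in Da (default 0.05).
#' @param fragment_leakage fraction of each parent target amount appearing
#'   as each degradation fragment (default 0: perfect protection).
#' @param n_decoys number of decoy noise peaks per spectrum (default 40).
#' @param decoy_noise_level scale of decoy peak intensities (half-normal
#'   sigma; default 7).
#' @param mz_window instrument m/z window (default `c(700, 5000)`).
#' @param probe_pmol amount of probe loaded per spectrum (default 0:
#'   probe peak omitted).
#' @param seed integer seed; fixed seed gives bit-identical output.
#' @param replicates default replicate count for single-condition runs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(response_factor = 10, cv_shared = 0.20,
                       cv_indep = 0.05, mz_jitter_sd = 0.05,
                       fragment_leakage = 0, n_decoys = 40L,
                       decoy_noise_level = 7, mz_window = c(700, 5000),
                       probe_pmol = 0, seed = NULL, replicates = 1L) {
  stopifnot(response_factor > 0, cv_shared >= 0, cv_indep >= 0,
            mz_jitter_sd >= 0, fragment_leakage >= 0, fragment_leakage <= 1,
            n_decoys >= 0, decoy_noise_level >= 0,
            length(mz_window) == 2L, mz_window[1] < mz_window[2],
            probe_pmol >= 0, replicates >= 1)
  structure(
    list(response_factor = response_factor, cv_shared = cv_shared,
         cv_indep = cv_indep, mz_jitter_sd = mz_jitter_sd,
         fragment_leakage = fragment_leakage, n_decoys = as.integer(n_decoys),
         decoy_noise_level = decoy_noise_level, mz_window = mz_window,
         probe_pmol = probe_pmol, seed = seed,
         replicates = as.integer(replicates)),
    class = "sim_config"
  )
}

# sdlog of a lognormal with median 1 and coefficient of variation cv
.lnorm_sdlog <- function(cv) sqrt(log1p(cv^2))

# Core spectrum draw; assumes the RNG stream is already positioned.
.sim_spectrum_draw <- function(species, amounts, cfg) {
  stopifnot(nrow(species) == length(amounts), all(amounts >= 0))
  out_mz <- numeric(0); out_int <- numeric(0)
  truth <- data.frame(label = species$label, sequence = species$sequence,
                      theoretical_mz = species$theoretical_mz,
                      amount_pmol = amounts,
                      true_intensity = amounts * cfg$response_factor,
                      stringsAsFactors = FALSE)
  S <- stats::rlnorm(1, 0, .lnorm_sdlog(cfg$cv_shared))
  E <- stats::rlnorm(nrow(species), 0, .lnorm_sdlog(cfg$cv_indep))
  jit <- stats::rnorm(nrow(species), 0, cfg$mz_jitter_sd)
  keep <- amounts > 0
  out_mz <- species$theoretical_mz[keep] + jit[keep]
  out_int <- truth$true_intensity[keep] * S * E[keep]
  if (cfg$n_decoys > 0L) {
    dm <- stats::runif(cfg$n_decoys, cfg$mz_window[1], cfg$mz_window[2])
    di <- abs(stats::rnorm(cfg$n_decoys, 0, cfg$decoy_noise_level))
    out_mz <- c(out_mz, dm)
    out_int <- c(out_int, di)
  }
  list(peaks = peak_list(out_mz, out_int), truth = truth,
       spot_factor = S)
}

#' Simulate one centroid spectrum
#'
#' @param species a `theoretical_species` data.frame (all m/z inside the
#'   configured window).
#' @param amounts numeric vector of loaded amounts (pmol), one per species
#'   row; species with amount 0 emit no peak.
#' @param cfg a [sim_config()].
#' @param seed overrides `cfg$seed`; `NULL` continues the current RNG
#'   stream.
#' @return List with `peaks` (a [peak_list()]), `truth` (data.frame:
#'   label, sequence, theoretical_mz, amount_pmol, true_intensity before
#'   noise) and `spot_factor`.
#' @export
simulate_spectrum <- function(species, amounts, cfg = sim_config(),
                              seed = cfg$seed) {
  stopifnot(is.data.frame(species))
  if (any(species$theoretical_mz < cfg$mz_window[1] |
          species$theoretical_mz > cfg$mz_window[2])) {
    stop("species outside the configured m/z window", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  .sim_spectrum_draw(species, amounts, cfg)
}

#' Simulate a blank analysis (decoy noise peaks only)
#'
#' @inheritParams simulate_spectrum
#' @return A [peak_list()]; feed to
#'   `estimate_noise(., method = "blank")` for detection-limit work.
#' @export
simulate_blank <- function(cfg = sim_config(), seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$n_decoys == 0L) return(peak_list())
  dm <- stats::runif(cfg$n_decoys, cfg$mz_window[1], cfg$mz_window[2])
  di <- abs(stats::rnorm(cfg$n_decoys, 0, cfg$decoy_noise_level))
  peak_list(dm, di)
}

# Map RNA motif tokens to the antiparallel complementary DNA probe
# (modifications pair like their parent base).
.dna_probe_for <- function(rna, tag_mass_delta = 0) {
  comp <- c(A = "T", C = "G", G = "C", U = "A")
  parents <- vapply(rna$tokens, function(t) {
    if (t %in% names(comp)) t else .registry$modifications[[t]]$parent
  }, "")
  oligo_spec(rev(unname(comp[parents])), strand = "DNA",
             end5 = "OH", end3 = "OH", tag_mass_delta = tag_mass_delta)
}

#' Build the pair of stoichiometry-standard assays
#'
#' Constructs the modified / unmodified pair of 15-mer RNA standards used
#' in stoichiometry experiments: a GGACU (or GG\[m6A\]CU) consensus motif at
#' the 5' terminus followed by a configurable 3' flank, each protected by
#' the same complementary DNA probe.  The default flank is a synthetic
#' placeholder sequence (the assay is insensitive to flank identity once
#' the flank is fully degraded).
#'
#' @param flank3 RNA flank appended 3' of the motif (default 10 nt, giving
#'   a 15-mer).
#' @param motif unmodified motif sequence (default `"GGACU"`).
#' @param motif_mod modified motif (default `"GG[m6A]CU"`).
#' @param probe_tag_mass neutral-mass offset of the probe ion tag (Da).
#' @param end5,end3 end chemistry of the full-length standards (default
#'   5'-OH / 3'-OH, the usual chemistry of synthetic RNA).
#' @return List with `unmod` and `mod` [protection_assay()] objects.
#' @export
stoich_assays <- function(flank3 = "CGUAUCACGU", motif = "GGACU",
                          motif_mod = "GG[m6A]CU", probe_tag_mass = 0,
                          end5 = "OH", end3 = "OH") {
  mk <- function(mot) {
    full <- parse_sequence(paste0(mot, flank3), strand = "RNA",
                           end5 = end5, end3 = end3)
    motif_len <- length(parse_sequence(mot, strand = "RNA")$tokens)
    motif_oligo <- subsequence(full, 1L, motif_len, "OH", "OH")
    protection_assay(full, 1L, motif_len,
                     probe = .dna_probe_for(motif_oligo, probe_tag_mass))
  }
  list(unmod = mk(motif), mod = mk(motif_mod))
}

# Combined, amount-annotated species table for a modified/unmodified
# mixture; isobaric rows (same label+sequence+ends) are pooled.
.mixture_species <- function(assays, cfg, mod_pmol, unmod_pmol,
                             min_frag_len = 2L) {
  one <- function(assay, pmol, molecule) {
    sp <- suppressWarnings(predict_species(assay,
                                           min_frag_len = min_frag_len,
                                           mz_window = cfg$mz_window))
    amt <- ifelse(sp$label == "target", pmol,
           ifelse(sp$label == "fragment", pmol * cfg$fragment_leakage,
           ifelse(sp$label == "probe", cfg$probe_pmol, 0)))
    sp$amount_pmol <- amt
    sp$molecule <- molecule
    sp
  }
  both <- rbind(one(assays$mod, mod_pmol, "modified"),
                one(assays$unmod, unmod_pmol, "unmodified"))
  key <- paste(both$label, both$sequence, both$end5, both$end3)
  agg <- both[!duplicated(key), , drop = FALSE]
  agg$amount_pmol <- as.numeric(tapply(both$amount_pmol, key, sum)[
    paste(agg$label, agg$sequence, agg$end5, agg$end3)])
  # probe is shared between the two assays, not doubled
  agg$amount_pmol[agg$label == "probe"] <- cfg$probe_pmol
  agg$molecule[agg$label == "probe"] <- "probe"
  agg <- agg[order(agg$theoretical_mz), , drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("theoretical_species", "data.frame")
  agg
}

#' Simulate a full stoichiometry experiment
#'
#' Emulates the mixture design used for stoichiometry calibration: a fixed
#' total RNA amount split between the modified and unmodified standard at
#' a series of nominal modified:unmodified ratios, with a set number of
#' replicate spectra per ratio.  Defaults reproduce the design
#' ratios 1:4, 1:2, 1:1, 2:1, 4:1 with n = 2, 2, 4, 4, 2 and 100 pmol
#' total.  For ratio r, amounts are `(total * r / (1 + r),
#' total / (1 + r))`.
#'
#' @param cfg a [sim_config()]; `cfg$seed` seeds the single RNG stream for
#'   the whole dataset (replicates advance the stream deterministically).
#' @param ratios nominal modified:unmodified ratios.
#' @param replicates replicate spectra per ratio (same length as
#'   `ratios`).
#' @param total_pmol total RNA per sample (default 100).
#' @param assays assay pair from [stoich_assays()].
#' @param min_frag_len minimum degradation-fragment length offered to the
#'   annotator.
#' @return A `simulated_dataset`: list with `peak_lists` (named list,
#'   `"r<ratio>_rep<i>"`), `design` (condition table), `truth` (per
#'   spectrum and species: amounts and pre-noise intensities), `species`
#'   (combined annotation target table; amounts dropped), `assays`,
#'   `config`.
#' @export
simulate_stoich_experiment <- function(cfg = sim_config(),
                                       ratios = c(0.25, 0.5, 1, 2, 4),
                                       replicates = c(2L, 2L, 4L, 4L, 2L),
                                       total_pmol = 100,
                                       assays = stoich_assays(),
                                       min_frag_len = 2L) {
  stopifnot(length(ratios) == length(replicates), all(ratios > 0),
            all(replicates >= 1), total_pmol > 0)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  peak_lists <- list()
  design <- list()
  truth <- list()
  species_ref <- NULL
  for (ci in seq_along(ratios)) {
    r <- ratios[ci]
    mod_pmol <- total_pmol * r / (1 + r)
    unmod_pmol <- total_pmol / (1 + r)
    sp <- .mixture_species(assays, cfg, mod_pmol, unmod_pmol, min_frag_len)
    if (is.null(species_ref)) {
      species_ref <- sp
      species_ref$amount_pmol <- NULL
      species_ref$molecule <- NULL
    }
    for (rep_i in seq_len(replicates[ci])) {
      nm <- sprintf("r%g_rep%d", r, rep_i)
      sim <- .sim_spectrum_draw(sp, sp$amount_pmol, cfg)
      peak_lists[[nm]] <- sim$peaks
      design[[nm]] <- data.frame(name = nm, nominal_ratio = r,
                                 replicate = rep_i,
                                 mod_pmol = mod_pmol, unmod_pmol = unmod_pmol)
      tr <- sim$truth
      tr$name <- nm; tr$nominal_ratio <- r; tr$replicate <- rep_i
      tr$molecule <- sp$molecule
      truth[[nm]] <- tr
    }
  }
  structure(
    list(peak_lists = peak_lists,
         design = do.call(rbind, c(design, list(make.row.names = FALSE))),
         truth = do.call(rbind, c(truth, list(make.row.names = FALSE))),
         species = species_ref, assays = assays, config = cfg),
    class = "simulated_dataset"
  )
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf(
    "<simulated_dataset> %d spectra over %d conditions (%d species offered)\n",
    length(x$peak_lists), length(unique(x$design$nominal_ratio)),
    nrow(x$species)))
  invisible(x)
}
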