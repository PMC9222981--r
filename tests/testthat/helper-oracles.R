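# Independent oracles and frozen reference values for the test suite.

# Textbook elemental compositions of the free nucleoside 5'-monophosphates
# (written out independently of the package's internal residue table, which
# stores chain residues = NMP minus water).
NMP_FORMULA <- list(
  RNA = list(A = c(C = 10, H = 14, N = 5, O = 7, P = 1),
             C = c(C = 9,  H = 14, N = 3, O = 8, P = 1),
             G = c(C = 10, H = 14, N = 5, O = 8, P = 1),
             U = c(C = 9,  H = 13, N = 2, O = 9, P = 1)),
  DNA = list(A = c(C = 10, H = 14, N = 5, O = 6, P = 1),
             C = c(C = 9,  H = 14, N = 3, O = 7, P = 1),
             G = c(C = 10, H = 14, N = 5, O = 7, P = 1),
             T = c(C = 10, H = 15, N = 2, O = 8, P = 1))
)

# Reference monoisotopic masses computed with an independent atomic-mass
# dataset (NIST isotope masses, via a Python mass calculator), frozen here.
REF_MONO <- c(AMP = 347.063084, CMP = 323.051851, GMP = 363.057999,
              UMP = 324.035867, H2O = 18.010565, HPO3 = 79.966331,
              CH2 = 14.015650, proton = 1.007276)

# Brute-force mass oracle: assemble the oligo composition from whole-NMP
# textbook formulas (sum NMPs, remove one water per phosphodiester bond,
# strip HPO3 for a 5'-OH, add HPO3 for a 3'-phosphate, apply modification
# deltas as formula differences), then multiply by the atomic-mass table.
# Independent bookkeeping route from the package's chain-residue sum.
oracle_mass <- function(tokens, strand = "RNA", end5 = "OH", end3 = "OH",
                        mass_type = "mono") {
  tab <- if (mass_type == "mono") protectMS::ATOMIC_MONO else
    protectMS::ATOMIC_AVG
  mods <- list(m6A = list(parent = "A", delta = c(C = 1, H = 2)),
               m1A = list(parent = "A", delta = c(C = 1, H = 2)),
               m5C = list(parent = "C", delta = c(C = 1, H = 2)))
  total <- c(C = 0, H = 0, N = 0, O = 0, P = 0)
  for (t in tokens) {
    if (t %in% names(NMP_FORMULA[[strand]])) {
      f <- NMP_FORMULA[[strand]][[t]]
    } else {
      m <- mods[[t]]
      f <- NMP_FORMULA[[strand]][[m$parent]]
      f[names(m$delta)] <- f[names(m$delta)] + m$delta
    }
    total[names(f)] <- total[names(f)] + f
  }
  h2o <- c(H = 2, O = 1)
  n_bonds <- length(tokens) - 1
  total[names(h2o)] <- total[names(h2o)] - n_bonds * h2o
  hpo3 <- c(H = 1, O = 3, P = 1)
  if (end5 == "OH") total[names(hpo3)] <- total[names(hpo3)] - hpo3
  if (end3 == "phosphate") total[names(hpo3)] <- total[names(hpo3)] + hpo3
  sum(total * tab[names(total)])
}

# Random RNA sequence of length n as a token vector, optionally with a
# modification substituted at a random position.
random_rna_tokens <- function(n, with_mod = FALSE) {
  tokens <- sample(c("A", "C", "G", "U"), n, replace = TRUE)
  if (with_mod) {
    i <- sample.int(n, 1)
    tokens[i] <- switch(tokens[i], A = "m6A", C = "m5C", G = "G", U = "U")
  }
  tokens
}

# Exhaustive minimum-total-|error| assignment of species to peaks (at most
# one peak per species, both used at most once, only pairs within
# tolerance).  Returns the minimal achievable total absolute error and the
# maximal number of matched pairs among minimal-error assignments of that
# size.  Small instances only.
brute_force_assignment <- function(theo_mz, obs_mz, tol) {
  ns <- length(theo_mz)
  best <- list(n = -1L, err = Inf)
  recurse <- function(si, used_peaks, n_matched, err) {
    if (si > ns) {
      if (n_matched > best$n ||
          (n_matched == best$n && err < best$err - 1e-12)) {
        best <<- list(n = n_matched, err = err)
      }
      return(invisible())
    }
    recurse(si + 1L, used_peaks, n_matched, err)        # leave species out
    for (pi in seq_along(obs_mz)) {
      if (pi %in% used_peaks) next
      d <- abs(obs_mz[pi] - theo_mz[si])
      if (d <= tol) {
        recurse(si + 1L, c(used_peaks, pi), n_matched + 1L, err + d)
      }
    }
  }
  recurse(1L, integer(0), 0L, 0)
  best
}

# Minimal annotation rows for metrics tests.
ann_row <- function(intensity, sn, label = "target", sequence = "GGACU") {
  data.frame(label = label, sequence = sequence, intensity = intensity,
             sn = sn, stringsAsFactors = FALSE)
}

# A small species table with arbitrary well-separated m/z values.
toy_species <- function(mzs, labels = rep("target", length(mzs))) {
  structure(
    data.frame(label = labels,
               sequence = paste0("S", seq_along(mzs)),
               strand = "RNA", end5 = "OH", end3 = "OH",
               tag_mass_delta = 0, length_nt = 5L,
               theoretical_mz = mzs,
               coordinates = paste0(seq_along(mzs), "-", seq_along(mzs) + 4L),
               stringsAsFactors = FALSE),
    class = c("theoretical_species", "data.frame"))
}

fixed_noise <- function(level = 1) {
  protectMS::estimate_noise(NULL, method = "supplied", level = level)
}
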