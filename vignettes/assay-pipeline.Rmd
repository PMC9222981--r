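---
title: "Models and methods behind protectMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind protectMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protectMS)
```

# The assay in one paragraph

A short DNA hybridization probe carrying an imidazolium ion tag (an ITO)
is annealed to the GGACU consensus motif of an RNA standard at a 2:1
probe:target ratio; single-strand-specific mung bean nuclease then
degrades everything unprotected, and the digest is read out in
reflectron-positive MALDI-TOF over 700–5000 *m/z*. A successful
protection leaves an intense 5-mer target peak (GGACU, or GG(m⁶A)CU
shifted by +CH₂ = +14.0157 Da); imperfect protection leaves degradation
fragments of the motif window. Because modified and unmodified targets
fly in the same spectrum, their intensity ratio estimates the
modification stoichiometry directly. protectMS models every step of that
readout that happens *after* the chemistry: theoretical masses, species
enumeration, peak annotation, and the assay's summary statistics.

# Mass model

Oligonucleotide compositions are assembled from chain residues
(nucleoside 5′-monophosphate minus water), plus one water per molecule;
a 5′-OH terminus subtracts HPO₃ from that base form and a 3′-phosphate
adds it. Modifications are elemental deltas on their parent residue
(m⁶A = adenosine + CH₂) held in an extensible registry
(`register_modification()`, or a `code,parent,delta_formula` CSV).
All masses derive from a single embedded atomic-mass table (monoisotopic
masses of the principal isotopes and IUPAC standard atomic weights,
six decimals), so results are bit-stable across platforms. Positive-mode
ions are modeled as \[M + zH\]ᶻ⁺ with the proton at 1.007276 Da;
the default is the singly protonated monoisotopic species, appropriate
for reflectron MALDI-TOF below ~5 kDa where isotopes are resolved.
Salt adducts and isotope envelopes are out of scope. The ITO's ion tag
is never printed as a structure in the assay literature, so the tag is
modeled as a non-negative neutral-mass offset (`tag_mass_delta`) on the
probe; the probe peak is annotated but never enters any ratio, so this
loses nothing.

# Protection model

`predict_species()` enumerates, for a protected window \[s, e\] on an
n-mer standard:

* the **intact target** — the window subsequence; an end created by
  cleavage gets the nuclease chemistry, an end coinciding with a
  terminus of the standard keeps the standard's own chemistry;
* **degradation fragments** — every contiguous proper subsequence of the
  window with length ≥ `min_frag_len` (default 2: mononucleotides fall
  far below the 700 *m/z* window), both ends with nuclease chemistry;
* the **probe**, and optionally the undigested full-length RNA.

Mung bean nuclease leaves 5′-phosphate / 3′-OH products, the defaults
for `nuclease_end5` / `nuclease_end3`; both are configurable because
annotated spectra do not by themselves pin the matched terminus
chemistry down. Fragments are enumerated only inside the protected
window by default — observed degradation peaks are target-derived, and
the unprotected flanks are assumed digested to sub-window pieces — with
`fragment_scope = "full"` available for whole-molecule enumeration.
MALDI cannot distinguish isobars, so fragments whose theoretical *m/z*
coincide within `merge_tol_da` (default 0.001 Da; exact sequence isomers
coincide to machine precision) are merged into one species that keeps
every coordinate interpretation in its `coordinates` field.

# Noise and annotation

The instrument's peak-processing software reports centroid intensities
without a published noise definition, so the package supplies a robust
default: `mad_low` takes the peaks at or below the median intensity and
returns 1.4826 × their median absolute deviation — insensitive to a
handful of strong analyte peaks riding on many small noise peaks. A
`blank` mode applies the same statistic to an entire blank spectrum (the
basis of the LOD), and `supplied` accepts an external value, which is
also the escape hatch when a spectrum has too few peaks or degenerate
(constant) intensities.

`match_peaks()` assigns peaks to species greedily by ascending absolute
mass error within a tolerance, each peak and each species used at most
once, ties broken toward the lower observed *m/z*. The default
tolerance of 0.5 Da reflects an externally calibrated MALDI-TOF at
1.5–5 kDa; a ppm mode is available. On instances up to six species the
greedy assignment is tested against an exhaustive
maximum-matching/minimum-total-error oracle; with species spaced more
than twice the tolerance apart (always true here — the closest pair,
GGACU vs. GG(m⁶A)CU, is 14 Da apart) the assignment is provably the
global optimum. No deisotoping or shared-peak splitting is done:
isobars were merged upstream, and monoisotopic theoretical masses match
monoisotopic centroids.

# Metrics

* **Stability ratio.** SR = 1 − Σᵢ I(fragmentᵢ)/I(target), summing
  every annotated degradation fragment with SN ≥ `sn_threshold`
  (default 10); the target itself must reach the threshold or the
  computation refuses ("target below quantification limit"). The phrase
  "the 1st, 2nd, …, nth most intense fragments" is read as *all*
  fragments passing the SN filter (a top-k cap is available). SR is a
  pure intensity ratio: invariant to uniform spectrum scaling, 1 when
  no fragment passes, negative (flagged, not clamped) when fragments
  outweigh the target.
* **Stoichiometry.** `measured_ratio()` divides the modified by the
  unmodified target intensity, both gated at SN ≥ 10. The shared spot
  factor multiplies both peaks and cancels exactly — the mechanism that
  makes ratios far more precise than single intensities.
* **Calibration.** `fit_calibration()` is ordinary least squares of all
  replicate measured ratios on nominal ratios, replicates as individual
  points (averaging per ratio first is a documented alternative the
  data do not force), free intercept by default with a forced-origin
  option. R² = 1 − SS_res/SS_tot about the mean response.
* **Group comparison.** `welch_ttest()` uses the unequal-variance
  statistic with Welch–Satterthwaite degrees of freedom; "unpaired
  t-test" alone does not determine the variance assumption and Welch is
  the safer default. No multiple-testing correction is applied (single
  planned comparisons).
* **Detection limits.** LOD = 3 × blank noise / response slope;
  LOQ = 10 × blank noise / slope (the SN = 10 condition), so
  LOQ/LOD = 10/3 identically. The response slope must come from a
  calibration in the same intensity units.

# What the simulator emulates

`simulate_spectrum()` draws, for species i with amount aᵢ pmol,

> Iᵢ = aᵢ · response_factor · S · Eᵢ,  S ~ lognormal(median 1, CV 0.20),
> Eᵢ ~ lognormal(median 1, CV 0.05)

with S drawn once per spectrum (the MALDI spot factor) and Eᵢ per
species; observed *m/z* = theoretical + N(0, 0.05 Da); decoy noise
peaks are uniform in *m/z* with half-normal intensities. The two-tier
structure is the simplest model consistent with the assay's two printed
precision figures: single-target RSDs of ~21–24 % near the LOQ *and* a
ratio calibration with R² ≈ 0.97 over ratios 0.25–4. Purely independent
~20 % noise per peak cannot do both — the ratio noise must be much
smaller than the intensity noise because both targets share a spot.
Lognormals are parameterized by median 1 so that ratios are
median-unbiased (the mean bias of a ratio of two median-1 lognormals at
CV 0.05 is ~0.25 %, far below the assay's precision).

Defaults that the assay description fixes: CVs 0.20 / 0.05, jitter
0.05 Da, window 700–5000 *m/z*, the mixture design (ratios 0.25, 0.5,
1, 2, 4; replicates 2, 2, 4, 4, 2; 100 pmol total, split
(total·r/(1+r), total/(1+r))). Defaults chosen here, once, as realistic
and then left alone: `response_factor` 10 intensity/pmol with
`decoy_noise_level` 7 and `n_decoys` 40, which puts a 10 pmol target
near SN 15–20, i.e. just above the assay's quantification limit, and a
blank-derived LOD of ~1–2 pmol; `fragment_leakage` 0 (perfect
protection) unless exercised. The published 15-mer standard sequences
are not reproduced in the assay's main text, so the default 3′ flank
(`CGUAUCACGU`) is an explicit synthetic placeholder and configurable —
flank identity is irrelevant once the flank is degraded below the mass
window, which is also why passing tests on simulated data say nothing
about probe–target hybridization efficiency, matrix effects, or
ionization bias between modified and unmodified species (assumed equal
here; the real assay cancels such bias only to first order).

A single RNG stream drives a whole dataset: the seed is set once and
replicates advance the stream deterministically, so a fixed seed gives
byte-identical outputs.

# Quantification QC in the pipeline

With decoy peaks present, the closest-peak rule can occasionally
(~0.2 % of simulated spectra) hand a target species a small decoy peak
that happens to sit nearer its theoretical *m/z* than the true,
jittered analyte peak. The resulting annotation fails the SN ≥ 10 gate
— which is precisely what that gate is for — and such a spectrum cannot
contribute a ratio. `analyze_stoich_dataset()` therefore omits spectra
whose targets fail quantification, records them in `$failures`, and
warns (`on_fail = "error"` aborts instead). Nothing is dropped
silently, and `measured_ratio()` itself always raises on a
sub-threshold input.

# Problem sizes and numerical choices

The test suite and the acceptance script use: 200 simulated five-ratio
experiments (2800 spectra) for the calibration summary, 1000 replicates
for the RSD and ratio-recovery checks, 50 spectra for the
leakage/stability-ratio demonstration, and brute-force oracles up to
6 species / 10-mer windows — sizes at which every stochastic summary is
stable to well inside the tolerances checked. Mass agreement between
the residue-sum route and an independent whole-nucleotide bookkeeping
oracle is required to 1e-6 Da; CSV round-trips preserve full double
precision (`%.17g`). Degenerate inputs are errors, not guesses: empty
peak lists for `mad_low`, constant intensities (MAD 0), zero-variance
t-test groups, identical nominal ratios in a calibration.

# Known limitations

* No isotope envelopes, adducts, multiply charged species or CID
  ladders; centroid spectra only (no peak picking from profile data).
* Digestion is modeled as candidate enumeration, not kinetics: the
  package predicts which fragments *could* appear, never how much of
  each; observed abundances are the data's job.
* The simulator's variance decomposition (spot vs. per-species) is
  calibrated to two printed precision figures only; real spot-to-spot
  structure may differ.
* Stoichiometry assumes equal ionization response of modified and
  unmodified targets; a +CH₂ difference makes this a good but not exact
  assumption.
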