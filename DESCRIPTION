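Package: protectMS
Title: Nuclease-Protection MALDI-MS Analysis of RNA Modification
    Stoichiometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computational pipeline for ion-tagged-oligonucleotide (ITO)
    nuclease-protection assays read out by MALDI-TOF mass spectrometry.
    Parses modified oligonucleotide sequences (e.g. N6-methyladenosine in
    a GGACU consensus motif), computes elemental compositions and
    monoisotopic or average masses, enumerates the theoretical digestion
    products of a probe-protected RNA, annotates centroid peak lists with
    mass-error and signal-to-noise statistics, and computes the assay's
    quantitative summaries: stability ratios, replicate statistics,
    modified-to-unmodified stoichiometry ratios, linear calibration fits,
    and detection limits.  A seeded simulator generates ground-truth
    annotated spectra that emulate spot-to-spot MALDI variability for
    benchmarking the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mzR,
    optparse
Config/testthat/edition: 3
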