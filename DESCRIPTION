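Package: zoomsr
Title: Collagen Peptide Mass Fingerprinting for Species Identification (ZooMS)
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Zooarchaeology by Mass Spectrometry (ZooMS): in-silico
    tryptic digestion of collagen type I chains, monoisotopic peptide mass
    arithmetic with hydroxylation/deamidation/oxidation state enumeration,
    discovery of species-discriminating peptide biomarker panels, MALDI-TOF
    spectrum preprocessing and signal-to-noise peak picking, per-sample
    taxonomic calling with cohort composition summaries, a neighbour-joining
    sanity check over collagen sequence divergence, and a fully seeded
    synthetic-data generator (collagen-like sequences with planted
    substitutions plus simulated MALDI spectra) so every pipeline stage is
    testable without external data. Ships a transcription of a published
    grouper (Epinephelus) biomarker panel as a worked reference fixture.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    mzR,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
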