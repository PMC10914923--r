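Package: sangeredit
Title: Quantitative Targeted RNA Editing Analysis from Sanger Chromatograms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies targeted A-to-I (read A-to-G) and C-to-U (read C-to-T)
    RNA editing from Sanger sequencing chromatograms of RT-PCR amplicons, as
    used in TRIBE/HyperTRIBE-style RNA-binding-protein interaction assays.
    Reads ABIF (AB1) trace files, integrates per-base four-channel peak areas,
    maps basecalls to a reference amplicon, computes per-site relative editing
    G/(A+G) (or T/(C+T)), applies background correction against control
    replicates and two replicate-based significance criteria, and summarises
    and plots editing profiles. Includes a plasmid-mix calibration analysis of
    peak-ratio linearity, a CAPS (cleaved amplified polymorphic sequence)
    cleaved-fraction assay with group comparison, and a synthetic chromatogram
    generator with known ground-truth editing for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
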