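Package: nnkqc
Title: Quality Control, Bias Diagnostics and Calibration for NNK
    Phage-Display Peptide Libraries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to assess and correct deviations from randomness in
    NNK-encoded phage-display peptide libraries sequenced by amplicon NGS.
    Provides a deterministic read simulator embodying the two dominant bias
    mechanisms in type-88 display systems (growth advantage of amber-codon
    clones in non-suppressing hosts; unequal phosphoramidite incorporation
    efficiency), strict barcode/flank/NNK read filtering, amber-aware
    translation and stop-class accounting, per-position nucleotide
    composition and degeneracy-normalized amino-acid distributions with
    analytic expectations, a calibration solver that prescribes compensating
    phosphoramidite stock ratios, and mixing calculations for
    adjusted-complexity library pools.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
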