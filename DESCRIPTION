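Package: lcampscan
Title: In Silico Screening for Linear Cationic Alpha-Helical Antimicrobial Peptides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening funnel for discovering linear cationic alpha-helical
    antimicrobial peptide (LCAMP) precursors in a proteome. Candidates are
    identified by precursor length, predicted secretion, absence of cysteine
    in the mature region, cationic amphipathic helix content measured by
    Eisenberg hydrophobic moment on an 18-residue sliding window, helix
    propensity, and AGGRESCAN-style aggregation propensity (Na4vSS). Also
    locates anionic helical proregions, derives majority-rule signal-peptide
    consensus sequences, and scans upstream DNA for NF-kB-like binding sites
    with Match-style core and matrix similarity scores. Includes a
    deterministic synthetic-proteome generator with planted precursors and
    stage-specific decoys for offline end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
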