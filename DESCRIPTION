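Package: promstruct
Title: Structural and Energetic Profiling of Archaeal Promoter Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Encodes TSS-anchored DNA sequences into per-position structural
    and energetic profiles (duplex stability, enthalpy, bendability, and
    BMHT wedge-model intrinsic curvature), builds TSS-aligned mean profiles
    with shuffled controls, classifies core promoters into TATA-conserved
    and TATA-degenerated groups by degenerate IUPAC motif matching, and
    scans upstream regions for promoter-like structural signals against a
    reference profile. Ships the dinucleotide parameter tables and a seeded
    synthetic promoter generator so every stage is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
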