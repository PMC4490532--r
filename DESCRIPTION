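Package: degracall
Title: Degradome (PARE) Analysis of miRNA-Guided Cleavage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A desk-scale pipeline for degradome (PARE) sequencing analysis
    of plant miRNA-guided transcript cleavage. Raw degradome tags are
    adapter-trimmed, filtered, depleted of ncRNA contaminants, collapsed to
    unique tags and mapped exactly to a transcript set to build per-transcript
    5'-end signature profiles. Candidate miRNA target sites are found with an
    ungapped plant-style complementarity score (mismatch 1, G:U wobble 0.5,
    penalties doubled over miRNA positions 2-13) and degradome-supported
    cleavage sites are classified into CleaveLand-style confidence categories
    0-4. The package also analyses miRNA precursors (perfectly matched
    degradome products, miRNA/miRNA*-directed self-cleavage, feedback loops,
    and duplexes whose two strands are both functional guides) and ships a
    synthetic degradome generator with full ground truth so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
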