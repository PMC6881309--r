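Package: pstwalk
Title: Palindromic Sequence-Targeted PCR Primer Design and Virtual Genome Walking
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for palindromic sequence-targeted PCR (PST-PCR), a
    genome-walking technique in which a walking primer anchors to short
    palindromic restriction sites via a 3'-terminal palindrome preceded by a
    fully degenerate block and an invariant 5' adapter. Provides PST and
    sequence-specific primer (SSP) construction and rule-based validation
    with degenerate-aware GC content, nearest-neighbor melting temperature,
    linguistic complexity, and combinatorial hairpin/primer-dimer screens;
    genome-wide palindromic-site scanning with spacing statistics and
    expected-product-length estimation under an i.i.d. base model; virtual
    two-round PST-PCR amplicon prediction on arbitrary templates including
    PST-PST side-product enumeration; and a seeded synthetic-template
    generator with exhaustive ground truth for validation. Includes a
    command-line interface for scanning, primer auditing, virtual PCR and
    fixture generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Sequencing, SequenceMatching, Alignment, PCR
RoxygenNote: 7.3.3
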