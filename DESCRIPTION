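Package: ribofs
Title: Detection and Quantification of +1 Ribosomal Frameshifting in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and quantifying +1 programmed ribosomal
    frameshifting in Saccharomyces cerevisiae coding sequences: scanning for
    known frameshift heptamers (Ty1-, EST3-, Ty3- and OAZ1-type), assembling
    dual-ORF gene models and trans-frame protein predictions, estimating
    frameshifting efficiency from frame-resolved ribosome-profiling P-site
    counts and from dual-luciferase reporter replicates, sliding-window
    synonymous-substitution conservation scans over codon alignments,
    detection of upstream stem-loop stimulators by a stacking-score dynamic
    program with DMS-reactivity consistency scoring, and simulators that
    generate every input with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
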