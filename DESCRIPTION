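Package: structvar
Title: Differential RNA Structurome Analysis from icSHAPE Probing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes per-nucleotide icSHAPE reactivities from reverse
    transcription stop counts, calls structurally variable windows and
    regions between developmental stages, quantifies their enrichment in
    transcript segments and in RNA-binding-protein motifs via exact
    position-weight-matrix p-values and Fisher tests, profiles structure
    around iCLIP binding sites, and links binding-site structural switches
    to maternal mRNA decay classes. Ships a seeded synthetic-data
    generator with planted ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
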