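Package: adatscan
Title: Detection and Comparative Analysis of I34-tRNA-Dependent
    Low-Complexity Protein Regions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study the role of inosine-34 (I34) tRNAs in
    translation.  Detects low-complexity protein regions rich in the
    eight amino acids whose codon boxes are decoded by I34-tRNAs
    (Thr, Ala, Pro, Ser, Leu, Ile, Val, Arg; "TAPSLIVR") with a
    running-window scan, scores coding sequences for enrichment in
    ADAT-sensitive codons, designs synonymous C-ended/G-ended reporter
    recodings with CAI and GC bookkeeping, computes cross-domain
    homolog-distribution statistics (group average ratios, permutation
    z-score tests, phylum normalisation, unicellular/multicellular
    comparisons, A34-tRNA gene-content correlations) and
    translation-efficiency enrichment tests (Fisher exact and
    permutation-proportion).  Seeded synthetic-data generators with
    truth tables make every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
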