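Package: chlorocub
Title: Codon Usage Bias Analysis for Chloroplast Coding Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for codon usage bias in chloroplast
    protein-coding genes: CDS extraction from FASTA or GenBank flat files
    and quality filtering; positional GC content (GC1/GC2/GC3, GC3s, GC12);
    relative synonymous codon usage (RSCU), relative frequency of synonymous
    codons (RFSC) and high-frequency codon classification; Wright's
    effective number of codons (ENC) with the ENC-GC3s expected curve; the
    codon adaptation index (CAI); parity-rule-2 and neutrality-plot
    diagnostics of mutation pressure versus selection; correspondence
    analysis of per-gene RSCU vectors; optimal-codon determination from
    ENC-ranked expression datasets; and comparison of host codon usage
    frequencies against model-organism tables in Kazusa format. Includes a
    seeded synthetic-CDS generator with controllable codon preference
    strength, third-position GC and GC12-GC3 coupling, so the whole
    pipeline is testable without genome downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    MASS,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
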