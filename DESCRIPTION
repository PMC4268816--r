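Package: cubkit
Title: Codon Usage Bias Analysis for Transcriptome-Scale CDS Sets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing synonymous codon usage bias in sets of
    protein-coding sequences, such as the predicted CDS collection of a de
    novo assembled transcriptome. Computes per-gene indices (relative
    synonymous codon usage, effective number of codons, positional GC
    content, codon adaptation index, GRAVY hydropathy and aromaticity),
    dataset-level diagnostics of the mutation-selection balance (neutrality
    plot, ENC versus GC3s with Wright's expected curve, parity-rule-2 bias,
    correspondence analysis of RSCU), and determines translationally optimal
    codons by chi-square comparison of CAI-defined high- and low-expression
    gene pools. A parametric CDS simulator with controllable mutation bias,
    selection strength and expression structure supports end-to-end testing
    without external sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    MASS,
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
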