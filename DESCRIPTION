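Package: codonscope
Title: Codon Usage Bias Profiling and Mutation-Selection Diagnostics for
    Coding Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling codon usage bias in sets of coding
    sequences: nucleotide composition panels (GC, GC1, GC2, GC3s and
    synonymous third-position base fractions), classical bias indices
    (effective number of codons, codon adaptation index, codon bias index,
    GRAVY, aromaticity), relative synonymous codon usage (RSCU/RFSC) with
    preferred/high-frequency/optimal codon classification, heterologous
    expression host screening against codon usage frequency tables,
    mutation-versus-selection diagnostics (ENC plot, PR2 bias plot,
    neutrality regression, correspondence analysis of RSCU), entropy- and
    likelihood-based expression proxies (SCUO, MILC), and a seedable
    synthetic coding-sequence generator with recorded ground truth so the
    entire pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    vegan,
    seqinr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
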