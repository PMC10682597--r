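Package: cubtools
Title: Codon Usage Bias and Parasite-Host Codon Co-Adaptation Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies codon usage bias (CUB) in parasite coding sequences
    and its co-adaptation to a host's codon usage. Reads and quality-filters
    multi-FASTA CDS files for many parasites plus one host reference set;
    computes nucleotide composition diagnostics (GC by codon position,
    parity-rule-2 coordinates, neutrality regression), nine gene-level CUB
    indices (ENc in Wright's and a pseudocount-modified form, MILC, B, MCB,
    CAI, MELP, FOP, E), codon-level statistics (RSCU, similarity index SiD,
    relative codon deoptimization index RCDI), permutation-based dinucleotide
    over/under-representation z-scores under base, codon and synonymous-codon
    null models, PCA and clustering of RSCU profiles, and the field's standard
    diagnostic plots. A deterministic synthetic CDS generator supports fully
    offline testing, and a pipeline driver orchestrates the whole workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    ggplot2,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
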