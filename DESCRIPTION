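Package: codonbias
Title: Tissue-Specific Codon Usage Bias from Expression-Weighted Codon Demand
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies tissue-specific synonymous codon demand from coding
    sequences and RNA-seq counts. Counts elongator codons per CDS (excluding
    the initiator codon and the terminal stop), reduces multi-isoform genes to
    their longest CDS, ranks genes by enrichment of a focus codon set (default
    the ACT/ACC threonine codons), normalizes count matrices by median-of-ratios
    size factors, computes expression-weighted per-tissue codon usage scaled to
    [0,1] by its maximum over the 64 codons, and reports per-codon tissue versus
    genome usage ratios. Includes a seeded synthetic-data generator (CDS catalogs
    with planted synonymous-codon preferences and negative-binomial count
    matrices) with closed-form expected bias, so every pipeline stage is
    verifiable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    DESeq2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
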