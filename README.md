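# codonbias

Tissue-specific codon usage bias from expression-weighted codon demand.

## What it is for

Translation speed and fidelity depend on the match between an mRNA's codons
and the decoding tRNA pool — including tRNA modifications such as
t^6^A/m^6^t^6^A on the threonine tRNAs that read the ACY codons ACT and
ACC. A tissue whose transcriptome is enriched for ACT/ACC-rich mRNAs is
therefore disproportionately sensitive to perturbations of those tRNAs.
`codonbias` quantifies this: from CDS sequences and an RNA-seq count
matrix it computes each tissue's **expression-weighted codon usage** and
compares it with the genome baseline as a per-codon ratio.

For each CDS, elongator codons are counted (the initiator codon and the
terminal stop are excluded — only codons read by elongating tRNAs count),
giving per-CDS frequencies *f_g(c)*. With normalized counts *n_g,t*
(median-of-ratios size factors), a tissue's usage is

    U_t(c) = sum_g  n_g,t * f_g(c)           (genes g, codon c)

Each usage vector is scaled by its maximum over the 64 codons,
*u_t(c) = U_t(c) / max_k U_t(k)*, and compared with the equally scaled
genome aggregate *u_G(c)*:

    bias_t(c) = u_t(c) / u_G(c)

`bias_t(c) > 1` means tissue *t* over-uses codon *c* relative to the
genome. The package also ranks genes by the fraction of a focus codon set
(default {ACT, ACC}), and ships a seeded synthetic-data generator with a
closed-form expected bias so the whole pipeline is verifiable offline.

## Worked example

Simulate a 300-gene, 3-tissue dataset in which the fat body prefers
ACT/ACC three-fold within the threonine family, then run the full
pipeline using each tissue's differentially expressed genes:

```r
library(codonbias)

spec <- sim_spec(n_genes = 300, enrichment = c(fat_body = 3), seed = 1)
simulate_dataset(spec, "demo")

report <- run_pipeline(list(
  cds_fasta = "demo/cds.fa",
  counts    = "demo/counts.tsv",
  gene_lists = list(wing_disc = "demo/de_wing_disc.txt",
                    fat_body  = "demo/de_fat_body.txt",
                    muscle    = "demo/de_muscle.txt"),
  out_dir   = "demo/out"
))
report
#> <bias_report> 3 tissue(s), focus set {ACT, ACC}, threshold 1.1
#>              ACT    ACC flagged
#> wing_disc 0.8852 0.9612       0
#> fat_body  1.2643 1.1348       1
#> muscle    0.8630 0.8578       0

round(expected_bias(spec), 4)
#>              ACT    ACC
#> wing_disc 0.8571 0.8571
#> fat_body  1.2857 1.2857
#> muscle    0.8571 0.8571
```

The pipeline recovers the planted structure: the fat body's ACT and ACC
ratios sit near the analytic expectation of 1.29 and only the fat body is
flagged; the unenriched tissues fall below 1 because the genome baseline
includes the fat-body-enriched genes. `demo/out/` now holds
`genome_usage.tsv`, one `<tissue>_usage.tsv` per tissue (64-row,
max-normalized), `size_factors.tsv`, `bias_report.tsv` and
`bias_report.json`; rerunning reproduces them byte-identically.

A 30-gene fixture of the same layout is bundled under
`inst/extdata/synthetic_example/` for quick experiments, and
`exec/codonbias` exposes `count`, `rank`, `usage`, `bias`, `simulate` and
`pipeline` subcommands for shell use.

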