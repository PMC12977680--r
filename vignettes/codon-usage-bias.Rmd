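---
title: "Tissue-specific codon usage bias: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tissue-specific codon usage bias: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonbias)
```

## The question the package answers

Synonymous codons are not used interchangeably. Because different tRNA
isoacceptors (and their chemical modifications, such as t^6^A/m^6^t^6^A at
position 37 of ACY-decoding threonine tRNAs) decode different codons, a
tissue whose transcriptome is enriched for, say, ACT- and ACC-rich mRNAs
places a distinctive demand on the tRNA pool. `codonbias` quantifies that
demand: given CDS sequences and an expression matrix, it asks *how does the
codon usage of a tissue's transcriptome compare with the codon usage of the
genome as a whole?*

## The measure, step by step

1. **Elongator-codon counting.** For each CDS, in-frame codons are counted
   from the **second** codon onwards — the initiator is decoded by the
   initiator tRNA, not by an elongating tRNA — and the terminal codon is
   excluded iff it is a stop triplet. Codons containing `N` are skipped and
   removed from the denominator so they cannot bias frequencies. The 64-slot
   vector retains the stop slots (at zero for any valid CDS) so the later
   "maximum over all 64 codons" normalization is literal.
2. **One isoform per gene.** Genes with several transcripts are reduced to
   the longest CDS; equal lengths are broken by the lexicographically
   smallest transcript id, so the reduction is reproducible. Without this
   step multi-isoform genes would be counted several times.
3. **Per-CDS frequency.** `counts / total_elongator`, summing to 1 over the
   61 sense codons.
4. **Count normalization.** Columns of the expression matrix are scaled by
   median-of-ratios size factors (the median, per column, of each gene's
   ratio to its geometric-mean pseudo-reference across columns), the
   standard bulk RNA-seq depth correction. Pre-normalized matrices are
   accepted via `pre_normalized = TRUE`.
5. **Expression weighting.** A tissue's raw usage of codon *c* is
   `sum_g count[g, tissue] * freq_g[c]` over the genes considered —
   deliberately the per-CDS *frequency*, not the raw codon count, so a
   highly expressed short gene and a highly expressed long gene contribute
   in proportion to expression, not length.
6. **Max-normalization.** The summed usage of each codon is divided by the
   maximum across all 64 codons, scaling to [0, 1]. This removes the
   arbitrary overall scale (sequencing depth, gene-set size) and makes
   tissues directly comparable.
7. **Bias ratio.** For each codon,
   `tissue_scaled[c] / genome_scaled[c]`, where the genome baseline is the
   *unweighted* aggregate frequency over all longest-isoform CDS,
   max-normalized the same way. A ratio above 1 means the tissue's
   transcriptome over-uses that codon relative to the genome.

```{r example}
fd <- system.file("extdata", "synthetic_example", package = "codonbias")
report <- run_pipeline(list(
  cds_fasta = file.path(fd, "cds.fa"),
  counts = file.path(fd, "counts.tsv"),
  gene_lists = list(fat_body = file.path(fd, "de_fat_body.txt")),
  tissues = "fat_body",
  out_dir = tempfile("codonbias_")
))
report$ratios[c("ACT", "ACC"), ]
```

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `min_elongator` (ranking) | 50 codons | fractions computed on very short CDS are noise; 50 elongator codons bounds the binomial SD of a ~1–3% codon fraction below ~2.5 percentage points. Configurable. |
| `ratio_threshold` (focus flags) | 1.1 | see below. |
| `focus_set` | ACT, ACC | the ACY threonine codons decoded by tRNA-Thr-AGT, the pair affected by t^6^A modification state; any sense-codon set may be substituted. |
| `mode` (ratio) | `"scaled"` | ratio taken on max-normalized vectors, making it depth-invariant; `"frequency"` (sense-sum-normalized vectors) is offered for sensitivity analysis. The two differ only through the max slot, so conclusions about non-modal codons rarely change. |
| `max_zero_rows` (size factors) | 0 | the classical estimator uses only all-positive reference rows; raising it enables a pseudo-reference over sparse matrices (geometric mean of positive entries). |
| `strict` (pipeline) | `TRUE` | frameshifted or internally-stopped CDS abort the run; `strict: false` truncates to frame and counts leniently, for annotation noise one knowingly accepts. |

### Why the focus flag uses a threshold above 1

A tissue is flagged when **all** focus codons exceed `ratio_threshold`.
Conceptually the interesting event is "ratio above 1", but an estimated
ratio fluctuates around 1 under the null (no real preference shift), and a
strict `> 1` rule would flag roughly a quarter of null datasets by chance
alone (two near-independent codons, each above parity with probability
~1/2). The default threshold of 1.1 asks for an effect larger than the
sampling noise of typical inputs (hundreds of genes, CDS of a few hundred
codons) while remaining far below the ratios produced by genuine synonymous
shifts of 1.5x and up. Setting `ratio_threshold = 1` restores the literal
rule. The flag is a screen, not a test: the package deliberately attaches
no p-value, because the ratio's null distribution depends on gene number,
CDS lengths and expression dispersion in a way no closed form captures;
users needing inference should bootstrap gene sets.

## The synthetic-data generator

`sim_spec()` + `generate_catalog()` + `generate_counts()` emulate the
statistical structure the pipeline estimates, with known truth:

- **Codon preferences.** Each tissue has a probability vector over the 61
  sense codons: amino-acid weights (average proteome composition) times a
  within-family tilt favouring G/C-ending codons by `gc3_bias = 1.5` — a
  fly-like third-position bias that also makes the most-used codon (GAG)
  unique, so max-normalization has a stable anchor. Enriched tissues
  multiply the focus codons by `f >= 1` *within the threonine synonymous
  family, renormalized*, so amino-acid composition is fixed and only
  synonymous preference moves — exactly the signature a tRNA-modification
  effect would produce.
- **CDS.** `ATG` + i.i.d. codons from the gene's home-tissue preference +
  `TAA`; lengths uniform on 100–500 codons. i.i.d. draws carry no positional
  autocorrelation, no codon-pair effects, no GC isochores: the simplest
  structure sufficient to test the pipeline's estimands.
- **Counts.** Negative binomial with mean `depth` (1000) elevated `de_fold`
  (4x) in the home tissue, size parameter `dispersion` (10, i.e. CV^2 ≈
  0.1 above Poisson — ordinary bulk RNA-seq), optionally times planted
  per-column scale factors to exercise size-factor recovery. Genes are
  assigned home tissues round-robin, so each tissue's "DE list" is a third
  of the genes.
- **Truth.** `expected_bias()` gives the closed-form focus-codon ratio the
  pipeline should recover: with DE-list usage the tissue vector is the home
  preference itself; with all-genes usage it is the `de_fold`-weighted
  mixture; the genome baseline is the equal-weight mixture. Both are
  max-normalized before the ratio, mirroring the pipeline exactly.

What passing these tests shows — and does not. Recovery on synthetic data
demonstrates that the arithmetic chain (counting → weighting → scaling →
ratio) is correct and calibrated under the stated noise model. It does not
validate the biological inputs of a real analysis: isoform annotation
quality, DE-list composition, mapping bias, or codon autocorrelation in
real CDS, none of which the generator emulates.

## Numerical and degenerate-input choices

- Stop slots are zero under default counting; internal stops (lenient mode
  only) are recorded in their slots but never enter `total_elongator`.
- All-zero usage max-normalizes to all-zero with a warning rather than NaN.
- Codons absent from the genome baseline yield an *undefined* ratio (`NA`,
  listed in `undefined_codons`), never `Inf`; for real CDS sets this is
  the three stop codons.
- Frequencies declare `sum == 1` only to 1e-9; ratios of identical profiles
  are 1 to 1e-12 (pure arithmetic).
- Pipeline outputs are printed with fixed `%.10g` formatting, so identical
  inputs give byte-identical files.
- `seed` fixes catalog generation; counts use `seed + 1`, keeping the two
  draws reproducible independently.

Test problem sizes: the oracle recount runs on 1000 CDS up to 3000 nt; the
enrichment-recovery study uses 500 genes x 3 tissues at depth 1000 over 10
seeds per boost factor (1.5, 2, 3); null calibration uses 20 replicates of
300 genes. These sizes put Monte-Carlo error well inside the tolerances
asserted while keeping the whole suite under a minute of compute.

## Known limitations

- The ratio compares *usage profiles*, not amino-acid-conditional usage:
  a tissue expressing threonine-rich proteins will show elevated ACT/ACC
  without any synonymous preference shift. Restricting comparisons within
  synonymous families (RSCU-style) is out of scope here, by design — the
  pipeline reproduces the expression-weighted 64-codon measure, and the
  synthetic generator isolates synonymous effects instead.
- The genome baseline is unweighted by expression; with equal counts and
  heterogeneous CDS lengths, expression-weighted usage is proportional to
  the *mean* per-CDS frequency, which differs from the aggregate
  (length-weighted) genome frequency. This is intentional (the baseline is
  a property of the genome, not of a transcriptome) but worth remembering
  when ratios sit very close to 1.
- No significance testing; see the flag discussion above.
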