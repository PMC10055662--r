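# longsplice

Isoform quantification and splicing-heterogeneity statistics for cell- or
spot-barcoded Nanopore long-read RNA-seq.

Long reads cover whole cDNA molecules, so they can in principle tell which
isoform every molecule in every cell came from. In practice, Nanopore's
per-base error rate corrupts the cell barcode and UMI carried in each
read's softclip, sequencing errors split the copies of one molecule into
several apparent UMIs (*scattering*) or merge distinct molecules of a
highly expressed gene (*crowding*), 5' truncation hides transcript starts,
and short middle exons drop out of spliced alignments, faking novel
isoforms. `longsplice` is for researchers who have barcoded long-read
libraries (10x Chromium / Visium style) and want per-cell, per-exon
isoform counts they can trust, plus a statistical layer on top of them.

## What it does

**Preprocessing** — from a spliced BAM (softclips retained), a GTF and a
barcode whitelist:

1. softclip extraction with polyA detection; splice-site support
   filtering;
2. barcode assignment via an 8-mer index, an adaptively re-estimated
   positional prior, and infix edit distance (ambiguous minima are
   dropped);
3. UMI deduplication: reads are pooled into *meta-isoform groups*
   (chains inter-convertible by end truncation or mis-mapping of middle
   exons < 80 bp), their UMI windows scored by Needleman–Wunsch
   (+1/−1/−1) and clustered by iterative Louvain community detection with
   min-cut and edge-strength stopping rules;
4. truncation and mis-mapping correction by per-cluster representative
   isoforms and a global attribution table;
5. *scatter reduction*: cluster sizes are modelled as
   `C − 1 ~ NB(r, p)`, so `var(C) = β(mean(C) − 1)` with `β = 1/p`;
   implausibly small clusters are trimmed until the variance CI covers
   the model line.

**Statistics** — per cell and (meta-)exon, inclusion counts `E` and
informative counts `G` with NA-censoring of truncated ends; then the
Beta-Binomial model

```
E_c ~ Binomial(G_c, psi_c),   psi_c ~ Beta(alpha, beta)
mu  = alpha / (alpha + beta)            (bulk percent-spliced-in)
phi = var(psi) / [mu (1 − mu)]          = 1 / (alpha + beta + 1)
```

`phi` in [0, 1] separates intra-cell heterogeneity (low `phi`: isoforms
co-expressed within cells) from inter-cell heterogeneity (high `phi`:
binary, cell-exclusive usage). Differential splicing between two cell
groups is a generalized likelihood-ratio test of shared `(alpha, beta)`
(chi-square, 2 df) with Wasserstein effect sizes and Benjamini–Hochberg
FDR control.

A synthetic-data module (`simulate_umi_pool`, `simulate_reads`,
`simulate_cells`, `calibrate_error_model`) generates all of the above
regimes with full ground truth.

## Worked example

Simulate a clean two-isoform library, run the pipeline, and inspect the
counts:

```r
library(longsplice)

sim <- simulate_reads(n_cells = 6, mols_per_cell = 12,
                      error = error_model(0, 0, 0), min_umi_dist = 4,
                      seed = 12)
dir <- tempfile(); dir.create(dir)
write_sim_sam(sim, file.path(dir, "reads.sam"))
write_catalog_gtf(sim$catalog, file.path(dir, "annotation.gtf"))
write_whitelist(sim$whitelist, file.path(dir, "whitelist.txt"))

cfg <- pipeline_config(bam = file.path(dir, "reads.sam"),
                       gtf = file.path(dir, "annotation.gtf"),
                       whitelist = file.path(dir, "whitelist.txt"),
                       out_dir = file.path(dir, "out"),
                       beta = 2, merge = FALSE, n_boot = 0, min_cells = 2)
res <- run_pipeline(cfg)
head(res$counts, 4)
#>                cell gene_id exon  E  G
#> 1  AGCTAAACGCGCTTTT   geneA    1 12 12
#> 5  CCTGGCAATCTGCACA   geneA    1 12 12
#> 9  CTCCGTATTTATGCGC   geneA    1 12 12
#> 13 GTTAATGAGTTGCGGA   geneA    1 12 12
```

Each row is one cell × sub-exon: `G` molecules were informative for the
sub-exon and `E` of them spliced it in, so `E/G` is that cell's
percent-spliced-in. All 12 molecules of each cell cover sub-exon 1, so
the zero-error run recovers them exactly. Downstream:

```r
phi <- estimate_phi_table(res$counts, min_G = 5, min_cells = 2, n_boot = 50)
phi[, c("gene_id", "exon", "mu", "phi", "phi_lo", "phi_hi")]
#>   gene_id exon        mu        phi       phi_lo     phi_hi
#> 1   geneA    1 0.9864865 0.00009999 9.999000e-05 0.00009999
#> 2   geneA    2 0.9864865 0.00009999 9.999000e-05 0.00009999
#> 3   geneA    3 0.4855816 0.06402288 6.569853e-11 0.17905569
#> 4   geneA    4 0.9864865 0.00009999 9.999000e-05 0.00009999
```

Sub-exon 3 is the toy gene's cassette exon: its mean inclusion `mu` is
about 0.49 with a small dispersion `phi`, i.e. both isoforms co-occur
within cells rather than splitting the cell population. The constitutive
sub-exons sit at `mu` near 1 with `phi` pinned to zero.

A thin command-line wrapper ships in `inst/cli/longsplice.R`
(`Rscript longsplice.R {run,simulate} ...`); the R functions above are
the primary interface.

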