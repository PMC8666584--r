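# tracseq

Analysis of N7-methylguanosine (m7G) tRNA modification from chemical
reduction-and-cleavage sequencing (TRAC-seq), and of its downstream
consequences for mRNA translation, in R.

m7G sits in the variable loop of many human tRNAs (canonically G46,
written by METTL1/WDR4) and is read out chemically: NaBH4 reduction
followed by aniline cleavage breaks the backbone at modified positions,
so in a treated sequencing library cleavage sites appear as positions
with an excess of read *starts* relative to a non-treated control. The
package is for computational biologists analysing such experiments --
and for anyone who wants a fully synthetic, ground-truthed replica of
one to validate methods against.

## What it computes

For each mature position *i* of each tRNA, from the read-start pileup
(depth *d_i*, start count *s_i*):

- cleavage ratio `r_i = s_i / d_i` (masked below a 20-read depth floor),
- cleavage score `score_i = log2( r_treated_i / r_control_i )`
  (with a 1e-4 pseudo-ratio guarding zeros),
- m7G site calls: positions 46-48 with `score > 4` and treated
  `ratio > 0.1`, both strict.

Around the calls: mature-reference construction (intron excision + CCA),
per-tRNA methylation levels and paired Wilcoxon comparisons, site
motifs, tRNA expression under the exclusive-mapping rule
(`RPKM > 10,000` expressed filter, knockdown/control fold changes),
translation efficiency `TE = FPKM_polysome / FPKM_input`, translation
ratios `TE_kd / TE_ctrl`, the m7G-codon frequency *f* of each CDS
(fraction of codons decoded by m7G-modified tRNAs, e.g. AAG for
tRNA-Lys-CTT), Pearson correlation of *f* with translation change,
quantile-group and TE-class comparisons (Mann-Whitney), and a
synthetic-data module that generates every input with known truth.

## Worked example

A complete synthetic study -- simulate, call sites, quantify expression,
analyse translation -- in one call:

```r
library(tracseq)
run <- run_pipeline(pipeline_config(seed = 1))
print(run)
#> tracseq synthetic run (seed 1, config 16e15739)
#>   tRNAs simulated: 20
#>   m7G tRNAs called: 10 (truth: 10)
#>   paired methylation test p = 0.00195
#>   median expression FC: modified 0.6, unmodified 1
#>   Pearson r(f, log2 TR) = -0.222 (p = 7.66e-90)
#>   low-vs-high f group test p = 6.65e-69
#>   TE classes (decreased/increased/other): 2399/2094/3506
```

Reading the output: all 10 tRNAs simulated with an m7G site (out of 20)
are called, with no false positives. Halving site cleavage in the
simulated knockdown lowers every called tRNA's methylation level
(paired Wilcoxon p = 0.002). The knockdown arm scales m7G-tRNA
abundance by 0.6, and the measured median fold change of the modified
class is 0.60 versus 1.00 for unmodified tRNAs. In the translation
stage, genes' log2 TE ratios were simulated to decrease linearly with
their m7G-codon frequency *f*; the pipeline recovers the negative
correlation, the separation between low-*f* and high-*f* quartile
groups, and TE-decreased genes enriched for m7G codons.

`write_run_outputs(run, "out/")` writes the per-site score track, call
table, fold changes, per-gene TE table and a JSON report, all stamped
with the config hash. A thin CLI wrapper lives at
`inst/cli/tracseq.R` (`Rscript tracseq.R {simulate|run} --seed N
--outdir DIR`).

Individual stages are plain functions operating on tibbles -- see
`?compute_pileup`, `?call_m7g_sites`, `?count_trna_reads`,
`?m7g_codon_frequency` -- and the methods vignette
(`vignettes/tracseq-methods.Rmd`) documents the models, defaults and
their rationale.

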