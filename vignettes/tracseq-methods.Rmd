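---
title: "tracseq: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tracseq: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracseq)
```

## The biology and the measurement

N7-methylguanosine (m7G) is one of the most common tRNA modifications in
human cells. It sits in the variable loop -- canonically at G46 -- and is
written by the METTL1/WDR4 methyltransferase complex. Because m7G has no
direct reverse-transcription signature, it is read out chemically:
NaBH4 reduction converts m7G to an abasic-like site and an acetate--aniline
mix then cleaves the backbone there. In a sequencing library built from
cleaved RNA, a cleavage event shows up as a read whose alignment *starts*
at the cleaved position. Comparing a treated library against a non-treated
control of the same sample therefore localises m7G sites as positions with
excess read starts.

`tracseq` implements the complete downstream analysis of such an
experiment: mature-tRNA reference construction, read-start pileups,
cleavage statistics, site calling, tRNA expression quantification,
polysome-based translation efficiency, and the codon-frequency analysis
that links m7G-modified tRNAs to the translation of specific mRNAs -- plus
a synthetic-data generator that reproduces the statistical structure of
every stage so the whole pipeline can be validated at desk scale.

## Mature tRNA reference

tRNA reads are aligned to *mature* tRNA sequences: the predicted introns
are excised from each gene and the post-transcriptional `CCA` tail is
appended to the 3' end (`build_mature_trna()`). Intron coordinates are
1-based closed intervals on the unspliced gene sequence, carried in a
simple FASTA header dialect (`id isotype=Lys anticodon=CTT
introns=38-60`). Distinct loci producing identical mature sequences are
collapsed into one entry with all source ids recorded -- reads cannot
distinguish identical sequences, and the collapse is reversible from
`source_ids`. `U` is normalised to `T` on input so every sequence space in
the package is DNA-alphabet.

Codon decoding (`decoded_codons()`) is strict Watson--Crick by default:
the decoded codon is the reverse complement of the anticodon (tRNA-Lys-CTT
decodes AAG), which matches the worked case the analysis is anchored on.
Wobble expansion at codon position 3 (G34 also reading U-ending codons,
U34 also reading G-ending codons) is available behind `wobble = TRUE`; it
is off by default because the downstream codon-frequency analysis is
defined on the strict set and wobble inflates the set with codons whose
decoding efficiency is not comparable.

## Cleavage statistics and site calling

For every mature position `i` the pileup records the depth `d_i` (reads
overlapping `i`) and the start count `s_i` (reads beginning exactly at
`i`). The cleavage ratio is `r_i = s_i / d_i`, computed only where
`d_i >= min_depth` (default 20 reads per arm); shallower positions are
masked as `NA` rather than reported as 0, so lack of coverage can never
imitate lack of cleavage. The cleavage score contrasts arms:

    score_i = log2( max(r_treated_i, eps) / max(r_control_i, eps) )

with pseudo-ratio `eps = 1e-4`, chosen below any ratio observable at the
depth floor (1/20 = 0.05) so it only guards the zero case. An alternative
reading of the score as a ratio of logarithms,
`log2(r_treated)/log2(r_control)`, is implemented behind
`literal = TRUE`; it is not the default because for a typical enriched
site (`r = 0.3` vs `0.01`) it evaluates to about 0.26 and could never
clear the calling threshold of 4, while the quotient form gives 4.9.

A site is called as m7G when all three conditions hold strictly:
position in the variable-loop window 46--48 (1-based mature sequence
coordinates, which absorbs the +/-1 ambiguity of the cleavage chemistry),
`score > 4`, and treated-arm `ratio > 0.1`. The ratio threshold is applied
to the treated arm only: the control arm enters through the score. A tRNA
is m7G-modified iff it has at least one passing call.

The per-tRNA *methylation level* used for condition comparisons is this
package's own summary: the maximum cleavage score over the 46--48 window.
Conditions are compared with the Wilcoxon signed-rank test paired by tRNA
(exact null for n <= 15 without ties, normal approximation with
continuity correction otherwise); group contrasts elsewhere use the
two-sided Mann--Whitney U test with the same exact/approximate policy at
a pooled size of 12. Both are computed through `stats::wilcox.test`; the
test suite verifies the exact branch against full enumeration of the
2^n sign assignments and C(n, n_a) group assignments.

## tRNA expression

Expression libraries (demethylase-treated so reverse transcription runs
full length) are counted under the exclusive-mapping rule: per read, only
best-score hits survive; if those include both genomic loci and mature
tRNAs, the genomic hits are dropped; a read tied across `k` mature tRNAs
contributes `1/k` to each, so total counts are conserved exactly.
Expression is RPKM-normalised, a tRNA counts as expressed when
`RPKM > 10,000` (strict), and the analysis set for fold changes is
defined on the *control* condition so a knockdown-induced loss cannot
filter itself out. Fold change is `RPKM_kd / RPKM_control`, reported by
m7G class.

The bench-assay formulas ship alongside: `2^-ddCt` relative expression
(also serving MeRIP-qPCR enrichment with U6 reference and input
calibrator) and the LC-MS modification percentage (modified-nucleoside
peak area over the summed area of all detected nucleosides).

## Translation efficiency and codon dependence

`FPKM = count / (length_kb * total/1e6)` per library; translation
efficiency is `TE = FPKM_polysome / FPKM_input`, masked where the input
FPKM falls below `min_input_fpkm` (default 1 -- the ratio of two small
FPKM values is dominated by counting noise). The translation ratio is
`TE_kd / TE_control`, and genes are classed as TE-decreased /
TE-increased / other at `|log2 ratio| >= log2(1.5)` with boundaries
inclusive toward the extreme classes. The threshold behind the published
class sizes is not stated anywhere we could find, so it is an explicit
parameter (`te_threshold`); likewise the quantile for the low/high
codon-frequency groups defaults to `q = 0.25` because equal groups of
2018 out of roughly 8000 analysed genes imply quartile tails.

The m7G-codon frequency `f` of a CDS is the fraction of its in-frame
codons (frame fixed at 0, terminal stop excluded from both sums, internal
stops counted but flagged) that belong to the m7G codon set -- the union
of codons decoded by the called m7G tRNAs, counted uniformly rather than
weighted by tRNA abundance. Codon counting is delegated to
`Biostrings::trinucleotideFrequency(step = 3)`.

## What the synthetic generator emulates

The generator is the package's study stand-in, and its defaults are the
conditions every recovery statistic is quoted at.

**TRAC-seq** (`trac_sim_config()`): 20 tRNAs of 70--90 nt, half carrying
a designated G at a position drawn from 46--48; 2,000 source molecules
per tRNA per library. Cleavage is per-molecule Bernoulli: probability
0.3 at an m7G site in the treated arm, 0.01 background (non-treated arm,
and unmodified molecules at uniformly random internal positions). A
cleaved molecule emits the downstream fragment -- a read starting *at*
the modified position, matching the start-counting convention of the
pileup; an uncleaved molecule emits a full-length read. No published
cleavage-efficiency figure exists for this chemistry at G46, so 0.3/0.01
are declared defaults, surfaced in the config and chosen to put the
expected score (log2(0.3/0.01) = 4.9) in the realistic just-above-threshold
regime rather than saturating it. Demethylase treatment is modelled
implicitly (reads traverse the molecule; no other hard stops), and FASTQ
qualities are constant because the pipeline never reads them.

**Expression** (`expr_sim_config()`): per-tRNA absolute abundances are
log-normal (median 1e5 counts, log-SD 0.5), sequenced counts Poisson, and
knockdown scales every modified tRNA's abundance by 0.6. RPKM is computed
against the library's total mapped reads (2e7), held equal across arms:
tRNA reads are a minority of a small-RNA library, so losing ~20% of tRNA
mass does not move the library denominator. This is what makes the
unmodified class's fold change centre on 1.0 while the modified class
centres on 0.6; normalising against the tRNA-count sum instead would
push the unmodified class to ~1.25 by compositional closure.

**Translation** (`te_sim_config()`): 8,000 genes, CDS lengths 100--500
codons, per-gene target frequency `f ~ U(0.2, 0.6)` implanted *exactly*
(round(f x n) codons drawn from the m7G set, the rest from other sense
codons, shuffled; the measurement stack recovers `f` bit-for-bit). The
knockdown effect is linear: `log2 TE ratio = -beta f + N(0, sigma)` with
defaults `beta = 2`, `sigma = 0.2`. Counts for the four libraries are
negative binomial (dispersion 0.1, typical of bulk RNA-seq) around means
`mu_input` (log-normal, median 500), `mu_poly = mu_input x TE`, with
control TE log-normal (log2-SD 0.3) and input means unchanged by
knockdown (the study design this emulates saw only modest mRNA-level
changes).

The expected Pearson correlation between `f` and the *measured* log2 TE
ratio has a closed form under this model
(`expected_freq_te_correlation()`):

    r = -beta sd(f) / sqrt( beta^2 var(f) + sigma^2 + v_meas )

where `v_meas` is the delta-method counting variance, the per-gene mean
of `sum over 4 libraries (1/mu + dispersion) / ln(2)^2`. At dispersion
0.1 the counting term is not negligible (it roughly triples the noise
variance), which is why it belongs in the closed form; with
`dispersion = 0` the expression collapses to the pure
linear-model value. Across seeds the measured correlation sits within
about 0.02--0.03 of this value at n = 8,000.

**What it does not emulate:** sequencing error, adapters, PCR
duplication, alignment ambiguity (alignment tables are emitted directly;
SAM/BAM input is supported but the aligner itself is out of scope), real
cleavage kinetics, isoacceptor structure in the random tRNA bodies, and
biological covariation between codon usage and expression level. Passing
recovery tests therefore demonstrates correctness of the statistics
pipeline under its stated model, not robustness to artefacts of real
libraries.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere; positions are mature
  sequence indices, not Sprinzl numbering.
* Masked quantities are `NA`, never 0, and propagate (a gene or site
  masked upstream appears in no downstream statistic).
* Calling thresholds are strict inequalities; a site at exactly
  score 4 or ratio 0.1 is not called.
* Quantile-split ties are broken by `gene_id` order so group sizes are
  exactly `floor(q n)` and runs are reproducible.
* Multi-mapper ties are split fractionally (1/k) rather than assigned
  randomly: conserves counts and removes seed dependence.
* Every simulator output is a pure function of its config; per-stage
  seeds are derived from the master seed with small fixed offsets (kept
  within 32-bit integer range).
* Problem sizes in the test suite are scaled to the smallest n at which
  each property is statistically decidable (e.g. 2,000 reads/tRNA for
  site calling, 8,000 genes for correlation recovery, 2,000 genes per
  seed for the 10-seed class comparison).

## Known limitations

* The m7G codon set treats all called tRNAs equally; no weighting by
  tRNA abundance or wobble efficiency.
* The calling window is fixed to 46--48 by the method's definition;
  modifications elsewhere are invisible by construction.
* RPKM/FPKM only -- no TMM/median-of-ratios size factors; cross-library
  comparisons inherit FPKM's compositional caveats.
* `compare_methylation_paired()` requires every compared tRNA to have a
  scored window in both conditions; deeply divergent coverage between
  conditions must be handled upstream.
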