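---
title: "Integrating gene-body and enhancer H3K79me2 with expression: methods"
author: "k79re"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating gene-body and enhancer H3K79me2 with expression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem this package addresses

H3K79 dimethylation (H3K79me2), written exclusively by the
methyltransferase DOT1L, marks the bodies of transcribed genes. In
cardiomyocytes, loss of DOT1L deregulates hundreds of genes in both
directions, and the deregulation cannot be explained by gene-body
methylation alone: a sizeable share of the affected genes carry no
H3K79me2 in their bodies at all. `k79re` implements the integrative
analysis needed to dissect a second route of regulation — H3K79me2 on
distal *regulatory elements* (REs) — by combining five data types:

* a gene annotation (GTF),
* H3K79me2 ChIP-seq reads/peaks and differential peaks between control
  and knockout,
* H3K27ac ChIP-seq peaks per condition (RE candidates) with
  differential calls,
* a binned intra-chromosomal Hi-C contact matrix,
* a differential-expression table (RPKM per condition, log2FC, FDR).

The pipeline links REs to target genes, classifies genes by their
regulatory configuration, and asks which transcription-factor motifs
distinguish "silencing" from "activating" K79-REs.

## The adapted Activity-by-Contact score

Candidate REs for a gene are all H3K27ac peaks whose midpoint lies in a
5 Mb window centered on the gene's most-5' TSS (autosomes only; sex
chromosomes are excluded). With $A_e$ the peak signal of enhancer $e$
and $C_{e,g}$ the balanced Hi-C contact frequency between the peak
midpoint bin and the TSS bin (5 kb bins), the gene-specific activity
splits the enhancer's signal across its candidate target genes $G_e$:

$$A_{e,g} = A_e \frac{C_{e,g}}{\sum_{j \in G_e} C_{e,j}}$$

and the adapted score is the *relative contribution* of the pair among
all candidates $E_g$ of the gene:

$$\overline{ABC}_{e,g} =
  \frac{A_{e,g}\,C_{e,g}}{\sum_{i \in E_g} A_{i,g}\,C_{i,g}}.$$

Scores of a gene's candidates therefore sum to exactly 1 whenever any
candidate has positive contact; pairs with score $\ge 0.02$ (inclusive)
are kept. Unlike the original ABC formulation there is no power-law
imputation for missing contacts: zero contact means zero score.
Promoter-overlapping peaks are ordinary candidates (a promoter can act
as an RE for a distal gene) and carry an `overlaps_promoter` flag.

Representative points are a design choice the score leaves open: we use
the peak midpoint for the enhancer and the most-5' TSS for the gene,
with the window half-open on the right
(`[tss − 2.5 Mb, tss + 2.5 Mb)`) so that membership is deterministic.

## Hi-C normalization

Contact matrices are loaded from plain-text triplet dumps
(`pos1 pos2 count`, bin-start coordinates) and balanced with the
Knight–Ruiz algorithm: the Newton iteration with an inner conjugate
gradient solve, seeking the diagonal scaling that makes every unmasked
row of $DAD$ sum to 1. All-zero bins are masked and left unscaled. The
convergence target is a relative row-sum tolerance of `1e-6`
(default); if the Newton iteration does not converge within the
matrix-vector budget the implementation falls back to symmetric
Sinkhorn–Knopp alternating scaling, and errors with the residual if
that also fails. Dumps that are already normalized can be passed
through with `prenormalized = TRUE`.

## Gene-body classification and stratification

For each gene body (the span from the most-5' to most-3' annotated
coordinate) we count overlapping H3K79me2 read intervals and the
fraction of bases with non-zero coverage. Replicates are combined by
summing counts and averaging fractions. A gene is *gene-body
methylated* (GB+) when the control-condition body has $\ge 50$ reads
and $\ge 0.20$ covered fraction, both inclusive; the read threshold is
applied as stated, without library-size normalization. Metagene
profiles rescale each body to 5 kb with 2 kb unscaled flanks in 20 bp
bins, oriented 5'→3', skipping zero-signal genes.

Stratified comparisons of log2 fold-change distributions use half-open
bins: gene-body covered fraction `{<1/3, [1/3, 2/3), >=2/3}` and K79-RE
count `{0, 1–5, >=6}` (the "6 or more" stratum inclusive), plus GB+
genes split by K79-RE presence. Pairs of strata are compared with the
two-tailed Kolmogorov–Smirnov test; the p-value uses the asymptotic
Kolmogorov distribution at effective size $n_x n_y/(n_x+n_y)$, which is
appropriate because strata are large; exact small-sample KS p-values
are out of scope (strata with fewer than two genes are skipped with a
warning).

## K79-REs and gene categories

An ABC-selected RE is a *K79-RE* when $\ge 10\%$ of its length is
covered by the union of differential H3K79me2 peaks; differential
H3K27ac status uses the same rule per direction. An RE covered by both
up- and down-regulated H3K27ac signal is labeled by the larger covered
fraction, ties going to `down` — a case the 10% rule can produce with
fragmented differential peaks, so the tie-break is fixed and
documented. Differential-H3K27ac REs are accounted to the genes they
interact with in the *control* regulatory map; only REs with no control
interaction at all contribute through their knockout links. RE identity
across conditions is matched by exact interval coordinates, which is
exact for the synthetic data and a documented simplification for real
peak sets (where reciprocal-overlap matching would be needed).

Gene categories combine DE direction (down/up at `|log2FC| >= 0.5`,
`FDR <= 0.05`, expressed at RPKM $\ge 1$ in at least one condition, all
inclusive), the GB flag, K79-RE linkage (distinct control-map K79-REs),
and differential-H3K27ac linkage. Counts per DE direction are reported
with percentages summing to 100, the tabular equivalent of an UpSet
plot.

## TRAP motif enrichment

Per-sequence TF affinity follows the biophysical TRAP model: for each
window $i$ of PWM width $W$ on both strands the mismatch energy is
$E_i = \lambda^{-1}\sum_j \ln(p_{\max,j}/p_{b_j,j})$ and the binding
probability $R_0 e^{-E_i}/(1+R_0 e^{-E_i})$; the affinity is the sum
over windows. The free parameters are the published TRAP defaults,
$\lambda = 0.7$ and $\ln R_0 = 0.584\,W - 5.66$; windows containing `N`
contribute 0. PWMs are built from count matrices with a +1 pseudocount.
Only TFs expressed at RPKM $\ge 1$ in either condition are tested.

Activating K79-REs (linked to down-regulated GB+ genes) are compared to
silencing K79-REs (linked to up-regulated GB− genes) with a one-tailed
Mann–Whitney test in each direction, exact by enumeration when the
pooled sample is small (n ≤ 12, no ties) and a tie- and
continuity-corrected normal approximation otherwise. The p-values of
*both* direction analyses are adjusted as a single Benjamini–Hochberg
family, and TFs with adjusted p $\le 0.05$ are significant. Pooling the
two directions into one family keeps the global-null probability of any
call near 5%; adjusting each direction separately would double it.

## What the synthetic generator emulates

`truth_config()` fixes the study conditions: 300 genes on two 10 Mb
autosomes plus a 5 Mb chrX (which exercises the autosome-only rule),
5 kb Hi-C bins, and planted gene classes with the effect sizes used
throughout: GB+RE+ down-regulated (log2FC $-1.5 \pm 0.3$), GB+ only
($-0.7 \pm 0.3$), silencing-RE up-regulated ($+1.0 \pm 0.3$) and null
($0 \pm 0.15$), in proportions 12/8/10/70%. A fifth of the null genes
carry the gene-body mark without expression change, mirroring
epigenetically compensated genes. Contacts decay as
$\mu_0 (d+1)^{-\alpha}$ with $\mu_0 = 5$, $\alpha = 1.2$, and planted
RE–promoter pairs boosted 5-fold — values chosen once as a realistic
short-range contact profile for 5 kb bins. RNA-seq counts are negative
binomial (3 vs 3 replicates, dispersion 0.01, the low biological
variability of sorted cells from littermate animals); the generator
performs its own differential test — a pooled-variance moderated z-test
on log2 counts, exploiting that a common dispersion implies a common
log-scale variance, as dispersion-shrinking DE tools do — so the
pipeline remains a consumer of an upstream DE table. Silencing-RE
sequences receive five planted consensus copies
(`TGACGTCATC`) among random sequence; the PWM set holds the planted
motif plus 19 random decoys named by expressed gene ids.

What the generator does *not* emulate: mappability and GC biases, peak
caller artifacts, inter-chromosomal contacts, isoform structure,
realistic motif co-occurrence, or correlated replicate structure.
Closed-loop recovery therefore demonstrates internal consistency of the
pipeline's rules, not performance on real sequencing data.

Because planted REs sit near (5–25 kb) their target promoters while
genes are spaced ~67 kb apart, a minority of genes genuinely link to a
neighbor's K79-RE at background contact levels — the same multi-target
behavior the score produces on real data — so closed-loop class
recovery plateaus around 92–95%, not 100%.

## Numerical choices and degenerate inputs

* Interval arithmetic uses `GenomicRanges` (1-based closed) as the one
  internal convention; BED and triplet inputs are converted at the
  boundary.
* Feature labels are made exclusive with precedence
  promoter > UTR > exon > intron, evaluated jointly over genes, so
  overlapping genes resolve deterministically; the 400 bp promoter
  (±200 bp of the most-5' TSS) is the single promoter definition used
  everywhere.
* Expression quartiles rank by control RPKM with stable gene-id
  tie-breaks; quartile sizes differ by at most one.
* A zero ABC denominator (no candidate with positive contact) yields
  all-zero scores rather than NaN; zero-length REs and empty samples
  raise errors.
* Test-suite problem sizes: balancing oracles run on 50×50 matrices,
  enumeration oracles to total n = 8, and the closed loop at the
  default 300-gene genome — sizes at which the independent oracles are
  exact and the full suite runs in a few minutes.

## Known limitations

* Intra-chromosomal contacts only; candidate windows never span
  chromosomes.
* Gene-level TSS choice (most 5'); isoform-specific promoters are not
  modeled.
* RE matching across conditions is coordinate-exact (see above).
* The read-count threshold for GB classification is used as printed,
  not depth-normalized, so very deep or shallow libraries need
  rescaling upstream.
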