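---
title: "Methods: binned differential methylation analysis in methdiv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binned differential methylation analysis in methdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdiv)
library(dplyr)
```

# The analysis model

`methdiv` compares the DNA methylomes of two samples (a test cultivar A
against a reference B) from per-cytosine bisulphite read counts, and couples
the resulting differentially methylated regions (DMRs) to gene expression
and small-RNA abundance.

## Methylcytosine calling

Bisulphite treatment converts unmethylated cytosines to uracil (read as T);
methylated cytosines resist conversion. At a site covered by $x = m + n$
reads, of which $m$ call methylated, the null hypothesis is that the site is
unmethylated and every methylated call is a conversion failure. With
non-conversion probability $e$, the P value is the inclusive upper binomial
tail

$$P = \Pr(X \ge m), \qquad X \sim \mathrm{Binomial}(x,\, e).$$

$e$ is estimated as the read-weighted pooled fraction
$\sum m / \sum (m+n)$ over all sites of a contig known to be unmethylated —
in plants the chloroplast genome, in the synthetic cohort a labelled control
contig. Read-weighted pooling is robust at low per-site depth, where a mean
of per-site ratios would be dominated by shallow sites. A site is called a
methylcytosine (mC) when $P \le \alpha$ **and** its depth is at least
`min_depth`; defaults are $\alpha = 0.001$ and depth 5, both inclusive. The
inclusive tail means $m = 0$ gives $P = 1$, so no site without a methylated
read can ever be called.

Sequence context is classified 5'→3' on the strand carrying the cytosine:
CG if the next base is G, otherwise CHG if the base after next is G,
otherwise CHH (H = A, C or T). Cytosines within two bases of a chromosome
end are classified on the bases available (CHH when undecidable) and
flagged. Opposite-strand CG sites are *not* merged: strand-resolved
methylation is part of the summaries, so symmetric-CG pooling is off.

## DMR detection

The genome is tiled with non-overlapping 100-bp bins. A cytosine site
contributes to its bin only if it is covered by at least five reads in
*both* samples. Per bin, read counts are pooled and the bin methylation
level is $100\sum m / \sum(m+n)$ — pooled counts rather than a mean of
per-site levels, so that the level difference and the test statistic are
computed from the same 2×2 table (a mean-of-sites mode exists via
`dmr_params(level_mode = "mean")`). Each bin is tested with a two-sided
Fisher exact test on

$$\begin{pmatrix} \text{meth}_A & \text{unmeth}_A \\
                  \text{meth}_B & \text{unmeth}_B \end{pmatrix},$$

and P values are corrected across **all** tested bins genome-wide in one
batch (not per chromosome, and not post-filter). A bin is a DMR when it
passes all three inclusive filters: at least 3 mCs, absolute level
difference at least 20 percentage points, and $q \le 0.01$. `diff` is
level(A) − level(B); positive is *hyper* (test sample hypermethylated).
The mC count uses the union rule — a site called in either sample counts —
which is the permissive reading; `mc_rule = "each"` switches to requiring
both.

Benjamini–Hochberg is the default correction. A SLIM-style mode
(`correction = "SLIM"`) rescales BH by a spline-estimated null proportion
$\pi_0$; the original sliding-linear-model fitting constants are not
published in enough detail to reproduce, so this mode documents itself as
approximate and BH stays the default.

## DMR–feature association and integration

A DMR is positioned relative to a gene or TE solely by its midpoint:
*genic* if the midpoint falls in the feature body, otherwise
*flank_upstream*/*flank_downstream* within 2 kb of the strand-appropriate
end. One DMR may associate with several features; each association is
independent. A gene associated with DMRs of both directions takes the
direction of the largest |diff| DMR; exact ties exclude the gene.

Differential expression uses a pragmatic replacement filter when no
upstream DE table is supplied: log2 fold change of replicate means
(pseudocount 0.01), a two-sided t-test on log2 abundances, and the
two-fold / $P \le 0.05$ rule. Integration statistics are:

* per-class log2 fold-change distributions with a two-tailed Wilcoxon
  rank-sum test against all genes (exact for tie-free combined $n \le 20$,
  otherwise normal approximation with continuity correction);
* directional enrichment — Fisher exact test of (hyper-associated ×
  downregulated) and (hypo-associated × upregulated) over all genes in the
  DE table, with the placement filter restricting which associations count;
* on/off classification: "on" at mean abundance ≥ 1, "off" below 0.1
  (abundance units, FPKM-like). These thresholds are a package choice —
  no standard definition exists — and both are exposed;
* TE density per gene class, with a two-sided permutation test
  (10,000 seeded label shuffles by default);
* small-RNA statistics: the fraction of mCs inside smRNA loci per context,
  the fraction of loci containing a mC, and the fold enrichment of locus
  density (loci per kb of gene-body territory, loci counted by midpoint)
  in a gene class relative to all genes, with a Fisher test on locus
  counts against territory sizes discretised to whole kb. Territory-length
  normalisation is one of the defensible choices here; an
  abundance-weighted variant would weight loci by read support instead.

## Profiles and density tracks

Metagene profiles aggregate items over 1-kb flanks in fixed 50-bp bins
(20 points per flank) and over the feature body in 40 equal *relative*
segments, mirroring minus-strand features so bin 1 is always 5'-most.
Features shorter than the body bin count are skipped and counted rather
than stretched. In fraction mode each track is normalised per context to
sum to 1 (a joint normalisation across contexts is a flag away).
Chromosome density tracks count items in fixed windows (default 100 kb,
the scale appropriate for a tens-of-Mb plant chromosome); Spearman rank
correlations quantify the association between mC density and gene/TE
density.

# The synthetic cohort generator

Real whole-genome bisulphite data for this kind of study are tens of
gigabytes and live in sequence archives; the package instead ships a
generator that emulates the *statistical* structure the analyses assume,
with machine-readable ground truth, so every stage can be benchmarked
end-to-end in seconds.

What it emulates, and the defaults chosen once for the reference cohort:

* **Genome**: 1 chromosome × 1 Mb of i.i.d. sequence at GC 0.43 (rice-like),
  plus a 20-kb fully unmethylated control contig standing in for the
  chloroplast. 200 genes (1–3 kb) and 150 TEs (0.2–1 kb) are placed without
  overlap; TEs cluster around the chromosome midpoint and genes toward the
  arms, emulating the pericentromeric repeat density that drives
  chromosome-scale methylation gradients.
* **Methylation levels**: methylated sites carry context levels CG 87.5,
  CHG 67.5, CHH 42 percent — midpoints of the ranges typical for rice
  methylomes. The methylated-site fractions (CG 0.80, CHG 0.60, CHH 0.13)
  were chosen so that, combined with the context abundances of random
  GC-0.43 sequence, the *fraction of mCs per context* lands in the
  CG ≈ 48, CHG ≈ 29, CHH ≈ 23 percent regime of plant methylomes. Inside
  TEs the methylated-site fraction is multiplied by 1.5 (capped at 1),
  making TEs hypermethylated relative to genes in every context.
* **Counts**: depth is Poisson with mean 30 (the coverage class of a
  modern WGBS experiment; Poisson rather than fixed depth so the min-depth
  filters are exercised), and methylated reads are Binomial with
  $p_\mathrm{eff} = \ell/100 + (1-\ell/100)\,e$, $e = 5\times10^{-4}$.
  At $\ell = 0$ this *is* the caller's null, so type-I control is testable
  exactly.
* **Planted DMRs**: 200 regions of one whole 100-bp bin each, level shift
  ±40 points, exactly half hyper (odd remainder hyper). Directions are
  assigned per gene neighbourhood, so a single gene is not simultaneously
  hyper- and hypo-shifted — mixed genes would receive no coherent
  expression or smRNA signal and would blur parameter recovery; at most
  one region group is split when the exact half/half quota forces it.
  By default the baseline (sample B) levels of planted sites are first
  clamped into the feasible range so the ±40 shift is exact at every site
  and the recorded delta is recovered without clipping bias
  (`clamp_baseline = FALSE` restores literal clip-at-[0,100] behaviour).
  A `planted_offset` knob shifts regions off bin boundaries to exercise
  partial-bin effects.
* **Expression**: per-gene baseline log2 abundance ~ Normal(3, 2) shared
  between samples, FPKM-like on the linear scale; genes whose body ±2 kb
  contains a planted hyper (hypo) DMR midpoint have sample-A log2
  abundance shifted by −2 (+2); lognormal replicate noise of 0.25 log2
  units across 3 replicates. The coupling is negative by construction:
  hypermethylation represses.
* **Small RNAs**: loci of 21–24 nt at a base rate of 3 per kb, rate ×1.7
  in hyper-DMR genes and ÷1.7 in hypo-DMR genes for sample A, abundance
  geometric-tailed ≥ 1. The recovered fold (hyper-class density over
  all-gene density) is expected somewhat below the planted 1.7 because
  the all-gene baseline itself contains the shifted classes.

Everything is driven by a single integer seed; identical configurations
produce byte-identical output files.

What it does **not** emulate: read-level artefacts (M-bias, clonal reads,
mapping bias), sequence composition beyond GC content (motifs, isochores),
replicate-level methylation variance (samples are single pooled
methylomes), overdispersed coverage beyond Poisson, and any real linkage
between TE families and smRNA production. Tests passing on this cohort
therefore validate the statistical machinery and its calibration, not
biological discovery on real data.

# Numerical and degenerate-input choices

* Fisher two-sided P uses the standard minimum-likelihood rule (sum of all
  hypergeometric outcomes no more probable than the observed table, with a
  1e-7 relative epsilon); a zero-depth sample yields P = 1 with a warning.
* All thresholds are inclusive (≤ for P/q, ≥ for depth, counts and
  differences).
* An all-identical expression vector gives a t-test P of 1 rather than an
  error; a single replicate disables the test and decides DE status on
  fold change with a warning.
* Zero-margin 2×2 tables report an undefined odds ratio and P = 1.
* Internal coordinates are 1-based inclusive everywhere; BED conversion
  (0-based half-open) happens only at file boundaries.
* Profile bins are assigned by `floor` arithmetic chosen so that the
  strand-mirroring identity holds exactly, not just asymptotically.

# Problem sizes

The reference benchmarking cohort is 1 Mb (~4.4 × 10^5 strand-specific
cytosines per sample, ~10^4 tested bins), which the full pipeline
processes in well under a minute; unit tests use a 100-kb variant. The
null-calibration checks use 10^5 simulated sites and 100 seeded
expression replicates. These sizes were picked so the entire suite runs
comfortably on a laptop while keeping every estimate's Monte-Carlo error
far inside the asserted bands.

# Known limitations

* SLIM mode is an approximation (see above); BH is the supported default.
* Adjacent significant bins are reported as separate DMRs; no merging or
  sliding windows.
* The DE replacement filter is deliberately simple; for real data a
  dedicated DE engine's output can be supplied instead.
* With a single chromosome pair of samples, q values are computed in one
  genome-wide batch; stratified corrections are out of scope.
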