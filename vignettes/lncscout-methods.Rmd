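---
title: "lncscout: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{lncscout: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

lncscout identifies candidate long non-coding RNAs (lncRNAs) in an
assembled transcriptome and characterizes them across omics layers:
differential expression between paired tumor and normal tissue, promoter
methylation, copy-number changes, promoter histone marks, conservation,
coexpression-based function prediction, cohort-level set enrichment, and
survival-based biomarker screening. This vignette records the models
behind each stage and the reasoning behind every tunable default, so that
a reader can judge what a passing test suite does — and does not — say
about real data.

## Coordinates and interval algebra

All internal coordinates are 0-based half-open; GTF I/O converts from and
to the 1-based inclusive file convention at the boundary. This is the
convention under which overlap arithmetic has no off-by-one cases:
`[0,100)` and `[100,200)` share no base and have gene-body distance 0
(touching bodies count as distance zero — adjacency is not separation).
Distance is measured between gene bodies (first exon start to last exon
end), not between TSSs; the choice is configurable where it matters (the
"sense" classification window) but body-to-body is the default because
the screening cascade's distance filter is a proximity filter on loci,
not on promoters.

Unstranded transcripts (`.` in the GTF) are parsed and retained in the
model, because dropping them is the screening cascade's job, not the
parser's.

## The candidate screen

The cascade applies, in order: transcript length strictly greater than
200 nt and a defined strand; zero same-strand exonic overlap with the
reference annotation (coding or non-coding); a split into mono- and
multi-exonic branches; for mono-exonic transcripts only, gene-body
distance strictly greater than 2,000 nt from any annotated transcript and
a maximum FPKM across samples strictly greater than 0.5; finally removal
of transcripts with a positive coding-potential score. All thresholds are
exclusive: a 200 nt transcript, a 2,000 nt gap and a 0.5 maximum FPKM all
fail.

Two readings of "overlapping annotation" are possible; lncscout uses
*same-strand exonic* overlap. The alternative (any-strand or gene-body
overlap) would eliminate the antisense and intronic classes entirely,
which the classification step is explicitly expected to produce, so it
cannot be the intended filter. Opposite-strand and intron-contained
transcripts therefore pass the overlap filter and are sorted out by the
classifier instead.

Positional classes are assigned with a fixed precedence — antisense >
intronic > sense > intergenic — because a transcript can satisfy several
definitions at once (e.g. an exon overlapping a coding exon on the other
strand while also sitting within 2 kb of a second gene). The precedence
is a determinism device, not a biological claim; it is documented here
because no convention is universal.

### Coding potential

The built-in score combines the longest-ORF fraction with a
Fickett-style codon-position asymmetry:

\[ s = 3\,(f_{\mathrm{ORF}} - 0.70) + 0.35\,(\min(b, 3) - 1.25) \]

where \(f_{\mathrm{ORF}}\) is the fraction of the transcript covered by
the longest ATG-initiated, stop-terminated reading frame (ORFs under
30 nt are ignored) and \(b\) is the mean, over the four bases, of the
ratio between the base's most- and least-populated codon position. Only
*closed* (stop-terminated) ORFs count: on uniform random sequence,
open-ended runs to the sequence end dominate the longest-ORF statistic at
short lengths (95th percentile of the covered fraction 0.67 open vs 0.62
closed at 300 nt, measured by simulation), which would make the score
unusably heavy-tailed. The centering constants are calibrated on that
random-sequence null so that the conventional sign convention holds:
scores above zero are coding-like, sequences without a qualifying ORF are
always negative, and a transcript whose ORF covers three quarters of its
length is always positive. This scorer is intentionally simple; when a
dedicated coding-potential tool has been run externally, its scores can
be injected per transcript (`coding_scores`) and take precedence.

## Differential expression

Counts are normalized with median-of-ratios size factors (rescaled to
geometric mean one so factors are comparable across runs), dispersion is
estimated per gene by the method of moments within each condition and
averaged, and the tumor-vs-normal contrast is a Wald test on the log2
ratio of normalized means with a delta-method standard error under the
negative-binomial variance \( \mu + \alpha\mu^2 \). A pseudocount of 0.5
in the fold change keeps all-zero groups finite; it is configurable.

The Wald statistic is referenced to a *t* distribution with
\(n_1 + n_2 - 2\) degrees of freedom rather than the standard normal.
With a plug-in moment dispersion at 8 + 8 samples the normal reference is
measurably anticonservative (empirical type-I 0.077 at nominal 0.05 on a
simulated negative-binomial null with dispersion 0.2), while the *t*
reference is calibrated (0.050). No shrinkage is applied to dispersions:
the estimator is validated by its calibration properties on simulation,
not by agreement with any particular production DE package, and at
desk-scale sample sizes the *t* correction absorbs most of the
estimation noise.

A gene is *called* (up or down) only when all three of |log2FC| > 1,
p < 0.05 and BH q < 0.05 hold — the triple criterion the screening
pipeline is built around. Pairing information between tumor and normal
samples is carried through the container but the default contrast is
unpaired; the planted-signal simulations showed no power shortfall at the
study's effect sizes, and an unpaired default keeps the test applicable
to unpaired designs.

## Epigenome integration

*Promoters* are the 2,000 nt strictly upstream of the TSS, excluding the
TSS base itself, oriented by strand. Methylation-expression correlations
are computed across all shared samples (tumor and normal pooled — the
pooled design is what gives the correlation its n = 16), and gene-CpG
pairs with Pearson correlation below −0.3 are retained; when several CpGs
pass for one gene, all pairs are reported and the most negative one is
flagged as the per-gene summary. Copy-number segments enter as calls with
q-values (segment significance is upstream of this package); a gene is
annotated with every significant (q < 0.25) segment its body intersects,
with a concordance flag for deletion/down and amplification/up.

TSS signal profiles accumulate peak signal into 100 nt bins spanning
±7,000 nt around the TSS, strand-oriented so negative offsets are always
upstream. A peak spreads its signal uniformly over its own width, so a
bin receives signal density times overlap; this makes the binned profile
equal a per-base accumulation exactly. On the minus strand the base
`[g, g+1)` maps to the reflected offset interval `[tss−g−1, tss−g)` —
the reflection of half-open intervals — which is what makes a strand
flip mirror the binned profile bin-for-bin; with the naive `tss−g`
convention the central bin would break the mirror symmetry.

## Coexpression and function

All gene pairs are scored by Pearson correlation; p-values from the *t*
transform are BH-adjusted over all pairs and edges with adjusted p below
the cutoff are kept. Markov clustering needs *similarity* weights, so the
adjusted p is mapped through −log10 (floored at a small positive
constant, with q clamped away from zero before the log): smaller adjusted
p means stronger coexpression means larger weight. Using the adjusted p
itself as a weight would invert that ordering.

The MCL iteration is the standard one: self-loops equal to each node's
maximum incident weight (1 for isolated nodes), column normalization,
then alternating expansion (matrix squaring by default) and inflation
(entrywise power, default 2, followed by renormalization) with pruning of
entries below 1e−5, until the flow matrix stops changing (tolerance
1e−8, cap 100 iterations, non-convergence returns the current
interpretation with a warning). Pruning is applied *after* the
post-inflation renormalization: pruning raw entrywise powers would zero
entire columns at high inflation, because `x^r` underflows the pruning
threshold for every `x < 1` once `r` is large. Clusters are read off the
attractor structure; a node attracted by several attractors joins the one
receiving the largest flow, ties broken lexicographically. Inflation
controls granularity (higher = finer); the default 2.0 is the
conventional choice and is exposed in the configuration.

Cluster-level function is assessed by a one-sided hypergeometric tail
test of each annotation term against the protein-coding background, BH
adjusted within cluster. Clusters below the minimum size (default 45
genes) are dropped before enrichment.

## Cohort validation (running-sum enrichment)

Genes of the validation cohort are ranked by signal-to-noise
\((\bar{x}_t - \bar{x}_n) / (s_t + s_n)\) with each group's standard
deviation floored at \(0.2\,|\bar{x}| + 10^{-8}\) (the conventional
regularization; the floor keeps near-constant genes from dominating the
ranking). The enrichment score is the signed maximum deviation of the
usual weighted running sum — hits add their normalized \(|m|^w\), misses
subtract \(1/(N - N_h)\) — and significance comes from phenotype
permutation with the add-one rule \((1 + k)/(n_{\mathrm{perm}} + 1)\), so
p-values are never zero. When the label vector admits at most
`n_perm` distinct assignments the script enumerates all of them instead
of sampling. Up- and down-regulated lncRNA sets are tested separately: a
positive score for the up set and a negative score for the down set is
the expected signature of a reproducible differential signal.

## Survival screening

The Kaplan–Meier estimator and the log-rank test are implemented
directly (and verified in the test suite against an independent,
established implementation to 1e−9). The 5-year analysis treats events
after 1,825 days as censored at the horizon. For biomarker screening each
differentially expressed lncRNA splits the cohort at an expression
cutoff; two rules are provided. The median rule (ties to the low group)
is assumption-free. The scan rule — the default, since published
cutoff-based survival analyses rarely commit to the median — evaluates
the 0.2–0.8 quantiles in 0.05 steps (13 cutoffs) and keeps the cutoff
minimizing the log-rank p. Scanned minimum p-values are anti-conservative
by construction, so every output row carries the number of cutoffs tried
and a Bonferroni-adjusted p over them; the null-cohort simulation in the
test suite documents the inflation rather than hiding it.

## The synthetic study

`simulate_all()` generates the complete input bundle with a ground-truth
manifest. Its defaults *are* the study conditions the pipeline is
designed around: 8 tumor + 8 paired normal samples; negative-binomial
counts (dispersion 0.2) with planted fold changes; a reference of 30
coding and 15 lncRNA genes on a 2 Mb two-chromosome toy genome laid out
on a slot grid that guarantees intergenic room; 12 planted candidates
apportioned over the four positional classes from the canonical
83.4/15.2/1.3/0.1 distribution (with at least one per class so every
class is exercised); two decoys per screening filter, each violating
exactly one filter; promoter CpGs anti-correlated with expression at
latent correlation −0.7 (a logistic transform of standardized expression
plus noise, scaled to stay in the near-linear regime so the realized
Pearson correlation survives the transform); one significant deletion
covering a planted down-regulated candidate; TSS peaks with class-ordered
intensity (coding 10 > annotated lncRNA 5 > candidate 2); and a
170-tumor validation cohort with exponential survival, one planted
hazard-ratio-3 lncRNA and ~15% uniform censoring with a median baseline
survival of 900 days. Forced-DE candidates carry |log2FC| 3.5 (so the
largest-effect report table is populated) and background DE genes 2.5 at
a 15% DE fraction — effect sizes a bulk tumor/normal comparison would
call large but unremarkable.

All randomness flows from one root seed through named substreams, so
adding a generator never perturbs another's draws, and every output is a
pure function of (seed, parameters). FPKM is derived from the simulated
counts, transcript lengths and library sizes (plus a constant background
library standing in for the unsimulated remainder of the transcriptome),
not drawn independently, so normalization and the expression filter see
internally consistent data.

What the generator does *not* emulate — and what passing tests therefore
do not establish about real data: realistic genome sequence (sequences
only control ORF content), overlapping gene models and multi-transcript
genes, batch effects and library-preparation artifacts, beta-value
heteroscedasticity of real methylation arrays, spatially correlated copy
number, read-level noise, or confounded survival covariates. The suite
establishes that each algorithm does what its definition says under
controlled conditions, not that the biological defaults are optimal for
any particular dataset.

## Problem sizes and numerical notes

The test suite and the acceptance script run the calibration experiments
at 2,000 genes for the null (type I within [0.03, 0.07] at nominal 0.05),
100 planted genes for power (≥ 80% at |log2FC| = 2, mean ≥ 50), 200–300
replicates for the retention, FDR and log-rank power simulations, 200
random instances per brute-force interval oracle, and 50 random graphs
against a dense-matrix MCL oracle — sizes chosen so the whole suite
completes in well under two minutes per module while keeping Monte-Carlo
error small relative to every asserted margin.

Degenerate inputs are handled explicitly rather than by accident:
constant genes are excluded from correlation graphs and clustering with
a warning; all-zero genes are flagged untestable and given p = 1; a
single-feature matrix falls back to Euclidean sample distance (between-
sample correlation is undefined there); zero-variance vectors in the
methylation screen skip the pair with a warning; an all-censored group
makes the log-rank test an explicit error rather than a NaN.
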