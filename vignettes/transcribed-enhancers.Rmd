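---
title: "Annotating transcribed enhancers from nascent transcription coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating transcribed enhancers from nascent transcription coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enhancertx)
```

## The problem

Enhancers fire before their chromatin marks settle, and the RNAs they
produce (eRNAs) are degraded within minutes. Nascent-transcription assays
such as TT-seq capture these short-lived transcripts: a brief metabolic
label followed by fragmentation yields strand-specific coverage of
everything RNA polymerase is making *right now*. `enhancertx` turns such
coverage — across a panel of cell lines with replicates — into a resource of
transcribed enhancers: where they are, how cell-type-specific they are,
which direction they fire, and which promoters they plausibly regulate.

Because the package is meant to be testable without any external download,
it ships a first-class synthetic-data generator whose outputs have the
statistical structure every stage assumes. All analysis functions are
tibble-in / tibble-out and compose with the pipe; model-like objects
(`pln_hmm`, `null_ensemble`) have `tidy()`, `glance()` and `autoplot()`
methods.

## The model, stage by stage

### Coverage and binning

Fragment midpoints are counted in consecutive 200-bp bins per strand
(`bin_midpoints()`). Binning smooths over uncovered positions inside
transcripts and makes lowly synthesized units detectable. All internal
coordinates are 0-based half-open; BED stays native on IO and GTF is
shifted on read/write.

### Genome segmentation

A two-state hidden Markov model with a Poisson–log-normal emission
(`fit_hmm()`) segments each strand into *transcribed* and *untranscribed*
states. The emission

$$P(k \mid \mu_s, \sigma_s) = \mathbb{E}_{Z \sim N(0,1)}\!\left[
  \mathrm{Pois}(k;\, e^{\mu_s + \sigma_s Z})\right]$$

is integrated by Gauss–Hermite quadrature with a fixed node count
(default 20); the number of nodes trades accuracy for speed and 20 nodes
keep the quadrature error far below the EM tolerance on count data of this
scale. Baum–Welch EM runs until the log-likelihood gain drops to `tol`
(default `1e-3` in the pipeline); the trace is retained and is
non-decreasing because the emission M-step starts its numerical
maximization from the current parameters. Numerical guards: states are
re-ordered by marginal emission mean after fitting (label switching), the
emission log-sd is floored at `1e-3` to prevent collapse to a pure
Poisson, and initialization comes from k-means (k = 2) on `log(1 + count)`
so a fixed seed gives a reproducible fit. Viterbi decoding
(`decode_tus()`) prefers the untranscribed state on ties — conservative TU
calls. Maximal transcribed runs become transcription units (TUs) at bin
resolution; `refine_boundaries()` sharpens boundaries to bp resolution by
a two-segment constant fit when per-bp coverage is available, and is a
no-op at pure bin resolution (boundaries already sit on bin edges).

### TU classification and eRNA calling

TUs covering at least 25% of a protein-coding gene on its strand and
touching one of its exons are mRNAs. Remaining non-coding TUs are placed
relative to the nearest opposite-strand coding gene by TSS position:
upstream-antisense (uaRNA, < 1 kbp upstream), convergent (conRNA,
< 1 kbp downstream), antisense (asRNA, > 1 kbp downstream inside the
gene), else intergenic. A TU whose TSS falls exactly on the sense TSS is
treated as upstream-antisense: divergent initiation from a shared
promoter, not convergent transcription. Non-coding TUs one bin apart are
merged (`merge_gaps()`, inclusive at 200 bp) to bridge mappability and
expression dropouts.

Intergenic and antisense TUs become eRNA candidates when their TSS
± 500 bp intersects a chromatin-state enhancer interval (an input; the
package learns no chromatin states). Guards against readthrough artifacts:

* intergenic eRNAs must have a divergent opposite-strand partner with a
  TSS gap of at most 750 bp (overlap allowed; the partner need not pass
  the expression threshold);
* antisense eRNAs absorbed into an mRNA/uaRNA readthrough run (successive
  same-strand gaps < 5 kbp) survive only with FPK at least twice that of
  the last 1 kbp of the upstream unit;
* no eRNA TSS may lie within 1 kbp of a coding TSS, and long antisense
  eRNAs reaching the host promoter are truncated 1 kbp downstream of the
  coding TSS.

Enhancer regions are then geometric constructions: intergenic regions span
the two divergent TSSs extended by 500 bp on each side; intragenic regions
cover 750 bp upstream to 500 bp downstream of the antisense TSS — always
exactly 1,250 bp. Per-line annotations are unioned across cell lines by
transitive interval merging with provenance (`merge_across_cell_lines()`).

### Normalization and activity

Size factors use the median-of-ratios estimator on gene counts only
(`size_factors()`); features with a zero in any sample are excluded from
the median. Enhancers and eRNAs inherit the gene-derived factors. Activity
is normalized FPK — depth-corrected counts per kilobase — with effective
length reduced by 750 bp for intragenic enhancers (their region includes
750 bp upstream of the TSS where no eRNA signal is expected), and
strand-aware counting: antisense-only for intragenic, both strands for
intergenic regions. A feature is *active* when replicate-averaged FPK
≥ 20 and every replicate reaches 15; promoters enter pairing at FPK ≥ 30.
The valley of the bimodal log2-FPK density over genes is available as a
diagnostic (`fpk_valley_cutoff()`), but the fixed cutoff of 20 is the
default for all samples. Replicate averaging and length normalization
commute here because replicates share feature lengths, so their order is
fixed (average after length normalization) and not configurable.

### Directionality and specificity

Promoter directionality compares normalized counts in TSS→TSS+1,000 bp
(sense) against TSS−1,150→TSS−150 bp (antisense), mirrored for minus-strand
genes; only promoters without an opposite-strand coding gene within
± 5 kbp are scored, and a promoter is bidirectional when both windows
reach 10 normalized counts. Enhancer directionality is the plus/minus
ratio over bidirectional intergenic regions shorter than 3 kbp, with a
preferred direction at ratio ≥ 3 or ≤ 1/3.

Two specificity scores over $n$ cell lines: the overall entropy score
$1 - H(p)/\log_2 n$ (0 = uniform, 1 = single line) and the per-line
Jensen–Shannon score $1 - \sqrt{JS(t, t^c)}$ against the one-hot pattern
of line $c$, both in bits. The overall score feeds matched-null
covariates; the JS score serves per-line analyses. Cross-line pattern
correlations (`cross_line_correlation()`) require bidirectional
observation (both counts ≥ 10) in at least 5 lines and a coefficient of
variation above 50%; the CV is computed on raw normalized counts, and both
members of the pattern pair must pass it — the filter's target vector is
genuinely ambiguous, so the stricter both-sided reading was fixed once.

### Enhancer–promoter pairing

Three strategies, all anchored at enhancer midpoints and gene TSSs
(5′-most TSS per gene), capped at 500 kbp: nearest active promoter (N, no
correlation filter), nearest active promoter on each side with Pearson
$r > 0.6$ on $\log_2(\mathrm{FPK}+1)$ across lines (CN), and all active
in-window promoters with $r > 0.6$ (CW), each CW pair flagged when a
transcribed promoter lies between enhancer and target. CN pairs are a
subset of CW pairs by construction, which the test suite audits on every
synthetic run. A pair is attributed to a cell line when both members are
active there; the paper implies but never states this rule, so it is a
package decision. Whether `r` uses replicate-averaged FPK was likewise
unstated; averaged values are used.

### Enrichment machinery

* **Super-enhancers** (`call_super_enhancers()`): peaks under 12.5 kbp
  apart are stitched; stitched regions are ranked by total signal, the
  rank/signal curve min-max rescaled, and the cutoff placed where the
  discrete slope (central differences) first exceeds 1 — the classic
  tangent-slope-one rule, written out here because the literature cites it
  by reference. Calls are invariant to uniform signal scaling.
* **Interaction support** (`chic_support()`): a pair is supported when an
  interaction with score ≥ 3.0 has its bait fragment covering the
  promoter TSS and its hit fragment overlapping the enhancer; pairs at
  ≤ 10 kbp are excluded from the denominator.
* **Matched nulls** (`sample_matched_ep_nulls()`,
  `sample_matched_snp_nulls()`, `region_overlap_enrichment()`): null sets
  preserve the observed set size and the joint decile-bin histogram of the
  matching covariates (activity and specificity for promoters; width and
  distance for regions; MAF, gene density and distance-to-gene for SNPs),
  with nearest-nonempty-bin fallback. Null regions flip to the other side
  of their promoter rather than clamping at a chromosome edge — clamping
  would pile nulls onto edge coordinates and bias the support rate.
  Empirical p-values use the plus-one rule
  $p = (1 + \#\{null \ge obs\})/(1 + n)$, never exactly zero. LD-count
  matching is off by default: the synthetic catalog carries no linkage
  structure.
* **Gene-class enrichment** (`fisher_enrichment()`): sample odds ratio
  $(ad)/(bc)$ with the $\infty$ convention, exact two-sided p.

## The synthetic-data generator

`generate_genome()` places non-overlapping two-exon genes and
enhancer-state intervals (intergenic and intragenic) with every state at
least 1 kbp — by default 3 kbp — from any coding TSS, and plants the eRNA
geometry each state will transcribe: a divergent pair with a 400-bp TSS
gap for intergenic states, one antisense eRNA for intragenic states. All
planted boundaries snap to 200-bp bin edges so that bin-resolution
segmentation can recover the truth exactly on noise-free coverage.
`generate_programs()` draws per-line synthesis rates (log-normal, with a
configurable fraction of strictly single-line enhancers), couples linked
genes to their enhancer's activity pattern (at most one link per gene, so
couplings are never overwritten), and assigns per-sample depth factors.
`simulate_coverage()` emits Poisson–log-normal bin counts,
$k \sim \mathrm{Pois}(\lambda e^{\sigma Z})$, so the marginal bin mean is
$\lambda e^{\sigma^2/2}$; `noise = FALSE` returns rounded expected rates.
`simulate_ancillary()` adds interaction tables (4-kbp tiles; every planted
link spanned with score ≥ 3, decoys below 3), SNP catalogs (trait SNPs
placed inside enhancers at a configurable enrichment factor, the remainder
rejection-sampled *outside* enhancer regions so that factor 1 really is
null), and peak signal proportional to enhancer activity with a heavy-tail
fraction for super-enhancer formation.

Defaults mirror the emulated study design: 14 cell lines × 2 replicates,
200-bp bins, about a third of enhancers single-line-specific,
upstream-antisense transcription in the TSS−150..−1,150 window (matching
the directionality quantification window, so the pipeline is
self-consistent), and a background rate of 0.05 counts/bin against
feature rates ≥ 5 — the signal-to-background ratio is not quantified in
the emulated setting and was fixed once at this plausible value.

What the generator does **not** emulate: mappability structure, GC or
sequence content (there are no reads, only bin counts), overlapping gene
models, transcript isoforms, RNA stability differences, genuine LD
between SNPs, and trans-chromosomal interactions. Passing tests therefore
demonstrate the correctness of the pipeline's logic under the model's own
assumptions, not robustness to every artifact of real sequencing data.

## Reproducibility and problem sizes

Every stage seed derives deterministically from one master seed;
`run_pipeline()` hash-logs its outputs, and rerunning a config reproduces
identical hashes. The test-suite problem sizes are the package's own
choices for a laptop-scale check: truth recovery runs on a 10-Mbp genome
with 100 genes and 150 enhancer states; HMM parameter recovery on 50,000
bins; pairing recall on ≥ 500 planted links across 14 lines; calibration
of both matched-null tests on 50 replicate runs with 79 null sets each.
The HMM is fitted on a capped contiguous chunk of bins (default 20,000)
and decoded genome-wide; fitting on a chunk changes the estimates
negligibly on homogeneous synthetic genomes.

Two empirical notes baked into the design: median-of-ratios equivariance
under scaling one sample by $c$ is exact only up to $c^{(n-1)/n}$ (the
per-feature geometric mean absorbs $c^{1/n}$), which the tests assert
exactly; and matched-null calibration degrades when many pairs share one
promoter (the observed statistic then has more variance than any
single-promoter-resampled null), so the calibration fixture keeps the
pairs-per-promoter ratio modest.

## Limitations

* The two-state HMM has no notion of transcript structure; a gene and its
  readthrough tail form one TU, separated only by the downstream filters.
* Enhancer-state intervals are trusted as given; false states propagate.
* The CHi-C and SNP machinery treats fragments and catalogs as inputs —
  no interaction calling, no LD computation.
* Boundary refinement needs per-bp coverage; with binned input,
  boundaries stay at bin resolution (±200 bp).
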