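# enhancertx

Transcribed-enhancer annotation and enhancer–promoter pairing from
strand-specific nascent-transcription (TT-seq-like) coverage.

Active enhancers transcribe short-lived enhancer RNAs (eRNAs) that
steady-state RNA-seq never sees. Given binned, strand-specific coverage of
newly synthesized RNA across a panel of cell lines, `enhancertx`:

1. **segments** each strand into transcribed/untranscribed states with a
   two-state hidden Markov model whose emission is Poisson–log-normal,
   `P(k | μ, σ) = E_Z[Pois(k; e^{μ+σZ})]`, fitted by Baum–Welch with
   Gauss–Hermite quadrature;
2. **classifies** transcription units (mRNA, uaRNA, conRNA, asRNA,
   intergenic) and calls **eRNAs** — divergent intergenic pairs (TSS gap
   ≤ 750 bp) and antisense intragenic units — against chromatin-state
   enhancer intervals, with readthrough filters (5-kbp merge, 2-fold rule);
3. builds **putative enhancer regions** (divergent TSS span ± 500 bp;
   intragenic regions exactly 1,250 bp), unions them across cell lines,
   and quantifies activity as normalized FPK with median-of-ratios size
   factors and the FPK ≥ 20 / ≥ 15-per-replicate activity rule;
4. scores **directionality** (sense/antisense and plus/minus ratios) and
   **cell-type specificity** — the entropy score `1 − H(p)/log2(n)` and the
   Jensen–Shannon score `1 − sqrt(JS(t, t^c))`;
5. pairs enhancers with promoters by **nearest** (N),
   **correlated-neighboring** (CN) and **correlated-window** (CW)
   strategies (active promoters FPK ≥ 30, Pearson r > 0.6 on
   log2(FPK + 1), window 500 kbp);
6. provides the **enrichment machinery**: super-enhancer stitching
   (12.5 kbp, slope-1 inflection cutoff), interaction (CHi-C-style)
   support of pairs (score ≥ 3.0, distance > 10 kbp), matched-null
   resampling for pairs and SNP sets with plus-one empirical p-values, and
   Fisher's exact gene-class enrichment.

A built-in synthetic-data generator (`generate_genome()`,
`generate_programs()`, `simulate_coverage()`, `simulate_ancillary()`)
emulates the full study design — 14 cell lines × 2 replicates of 200-bp
binned fragment-midpoint counts with Poisson–log-normal noise, planted
eRNA geometry, E–P couplings, interactions, SNP catalogs and peak signal —
so the entire pipeline is testable offline. Ground truth is carried along
for parameter-recovery tests.

## Worked example

A reduced end-to-end run (2-Mbp genome, 4 cell lines × 2 replicates):

```r
library(enhancertx)

cfg <- pipeline_config(seed = 1, chrom_length_bp = 2e6, n_genes = 20,
                       n_enhancer_states = 25, n_cell_lines = 4,
                       n_ep_null_sets = 50, n_snp_null_sets = 200,
                       hmm_fit_bins = 8000, hmm_max_iter = 25)
res <- run_pipeline(cfg)
res
#> <pipeline_result> 4 cell lines | 25 merged enhancers | N/CN/CW pairs 25/21/54 | 1 super-enhancers
```

All 25 planted enhancers are recovered, and the pair counts behave as
expected: every enhancer finds a nearest gene (N = 25), the correlation
filter keeps most flanking candidates (CN = 21 ⊆ CW = 54). The fitted
segmentation model separates background from signal cleanly:

```r
res$per_line$line01$model
#> <pln_hmm> 2-state Poisson-log-normal HMM, 6 EM iteration(s) (converged)
#>   emission means: 0.1243 (untranscribed) / 40.37 (transcribed)
```

Merged enhancer records keep provenance and kind; their activity matrix
drives the specificity scores — a ubiquitous enhancer scores near 0, a
single-line enhancer near 1:

```r
head(res$enhancer_specificity, 4)
#> # A tibble: 4 × 4
#>   feature   specificity js_best_line js_best
#> 1 MENH00001     0.00954 line02         0.291
#> 2 MENH00002     0.165   line03         0.466
#> 3 MENH00003     0.962   line01         0.932
#> 4 MENH00004     0.874   line04         0.867
```

The matched-null machinery detects the planted structure: E–P pairs are
supported by interactions far above width/distance/activity-matched
random pairs, and trait SNPs (planted at 3× enrichment) overlap enhancers
more than MAF/gene-density/distance-matched background SNPs:

```r
res$ep_null
#> <null_ensemble> fraction of E-P pairs with interaction support: observed 0.5556
#>   vs 50 matched nulls (median 0.1667), empirical p = 0.01961
res$snp_null
#> <null_ensemble> trait SNPs inside enhancers: observed 23 vs 200 matched nulls
#>   (median 8), empirical p = 0.004975
```

The score anchors are closed-form: a uniform 14-line pattern scores 0, a
one-hot pattern scores 1 on both the entropy and JS scales:

```r
c(entropy_specificity(rep(5, 14)),
  entropy_specificity(c(9, rep(0, 13))),
  js_specificity(c(9, rep(0, 13)), 1))
#> [1] 0 1 1
```

`autoplot()` works on fitted HMMs (log-likelihood trace), null ensembles
(null histogram vs observed) and super-enhancer calls (hockey-stick
curve); `plot_directionality()`, `plot_specificity()` and
`plot_pair_distances()` cover the main result tables.

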