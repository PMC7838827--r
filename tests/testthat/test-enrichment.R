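# Super-enhancer calling, interaction support, matched nulls and Fisher tests.

test_that("peak stitching uses the strict 12.5-kbp rule", {
  peaks <- tibble::tibble(chrom = "chr1", start = c(1000, 12000),
                          end = c(2000, 13000), signal = c(5, 5))
  # gap 10,000 < 12,500: stitched
  expect_equal(nrow(suppressWarnings(call_super_enhancers(peaks))), 1)
  peaks2 <- tibble::tibble(chrom = "chr1", start = c(1000, 22000),
                           end = c(2000, 23000), signal = c(5, 5))
  expect_equal(nrow(suppressWarnings(call_super_enhancers(peaks2))), 2)
})

test_that("a single extreme region is exactly what the slope rule flags", {
  peaks <- tibble::tibble(chrom = "chr1",
                          start = seq(0, by = 1e5, length.out = 50),
                          end = seq(0, by = 1e5, length.out = 50) + 1000,
                          signal = c(rep(1, 49), 100))
  se <- call_super_enhancers(peaks)
  expect_equal(sum(se$is_super), 1)
  expect_equal(se$total_signal[se$is_super], 100)
  # all-equal signals: no region exceeds slope 1
  peaks_eq <- dplyr::mutate(peaks, signal = 1)
  expect_equal(sum(call_super_enhancers(peaks_eq)$is_super), 0)
  # super calls are invariant to uniform signal scaling
  se2 <- call_super_enhancers(dplyr::mutate(peaks, signal = signal * 1000))
  expect_equal(se$is_super, se2$is_super)
  # fewer than 3 stitched regions: warning, all typical
  expect_warning(out <- call_super_enhancers(peaks[1:2, ]), "inflection")
  expect_false(any(out$is_super))
})

test_that("interaction support respects score and distance bounds", {
  enh <- tibble::tibble(enhancer_id = "E1", chrom = "chr1",
                        start = 50000, end = 51400, kind = "intergenic")
  prom <- tibble::tibble(chrom = "chr1", start = 100000, end = 120000,
                         strand = "+", gene_id = "g1")
  pairs <- tibble::tibble(enhancer_id = "E1", gene_id = "g1", distance = 49300)
  mk_int <- function(score) tibble::tibble(
    bait_chrom = "chr1", bait_start = 100000, bait_end = 104000,
    hit_chrom = "chr1", hit_start = 48000, hit_end = 52000, score = score)
  expect_true(chic_support(pairs, enh, prom, mk_int(3.0))$pairs$supported)
  expect_false(chic_support(pairs, enh, prom, mk_int(2.9))$pairs$supported)
  # distance at or below 10 kbp drops the pair from the denominator
  pairs_close <- dplyr::mutate(pairs, distance = 8000)
  out <- chic_support(pairs_close, enh, prom, mk_int(5))
  expect_equal(nrow(out$pairs), 0)
  expect_true(is.na(out$fraction_supported))
})

test_that("Fisher enrichment follows the sample odds ratio and exact p", {
  r1 <- fisher_enrichment(10, 10, 10, 10)
  expect_equal(r1$odds_ratio, 1)
  expect_equal(r1$p_value, 1)
  r2 <- fisher_enrichment(20, 10, 10, 20)
  expect_equal(r2$odds_ratio, 4)
  # exhaustive hypergeometric oracle for the two-sided p
  p_oracle <- {
    probs <- dhyper(0:30, 30, 30, 30)
    sum(probs[probs <= dhyper(20, 30, 30, 30) * (1 + 1e-7)])
  }
  expect_equal(r2$p_value, p_oracle, tolerance = 1e-6)
  expect_equal(fisher_enrichment(0, 10, 10, 0)$odds_ratio, 0)
  expect_equal(fisher_enrichment(10, 0, 0, 10)$odds_ratio, Inf)
  expect_error(fisher_enrichment(-1, 2, 3, 4), "nonnegative")
})

test_that("matched SNP sampling preserves size and covariate deciles", {
  withr::with_seed(30, {
    pool <- tibble::tibble(maf = runif(2000, 0.01, 0.5),
                           gene_density = sample(0:8, 2000, TRUE),
                           dist_nearest_gene = rexp(2000, 1e-4))
    obs <- pool[sample(2000, 300), ]
    idx <- enhancertx:::matched_sample_idx(obs, pool)
    expect_length(idx, 300)
    for (cov in names(pool)) {
      b_obs <- enhancertx:::decile_bin(obs[[cov]], pool[[cov]])
      b_smp <- enhancertx:::decile_bin(pool[[cov]][idx], pool[[cov]])
      h1 <- tabulate(b_obs, 10); h2 <- tabulate(b_smp, 10)
      expect_true(all(abs(h1 - h2) <= 1))
    }
  })
})

test_that("an observation beyond every null hits the plus-one floor", {
  # trait SNPs all inside enhancers, background all outside: nulls are 0
  enh <- tibble::tibble(chrom = "chr1", start = 0, end = 1000)
  trait <- tibble::tibble(chrom = "chr1", pos = sample(0:999, 20), maf = runif(20))
  backg <- tibble::tibble(chrom = "chr1", pos = sample(5000:99999, 500),
                          maf = runif(500))
  ens <- sample_matched_snp_nulls(trait, backg, enh, n_sets = 100, seed = 1,
                                  covariates = "maf")
  expect_equal(ens$observed, 20)
  expect_true(all(ens$nulls == 0))
  expect_equal(ens$p, 1 / 101)
  expect_true(ens$p > 0 && ens$p <= 1)
  expect_error(sample_matched_snp_nulls(trait, backg, enh, n_sets = 0, seed = 1),
               "positive")
  expect_error(sample_matched_snp_nulls(trait[0, ], backg, enh, n_sets = 10, seed = 1),
               "empty")
  expect_error(sample_matched_snp_nulls(backg, trait, enh, n_sets = 10, seed = 1),
               "smaller")
})

test_that("planted SNP enrichment is detected against matched nulls", {
  g <- small_genome()
  tr <- small_truth()
  anc <- simulate_ancillary(g, tr, seed = 31, enrichment = 5, n_trait = 400,
                            n_background = 4000)
  ens <- sample_matched_snp_nulls(dplyr::filter(anc$snps, set == "trait"),
                                  dplyr::filter(anc$snps, set == "background"),
                                  g$enhancers_truth, n_sets = 200, seed = 32)
  expect_lte(ens$p, 0.005)
  expect_gt(ens$observed, stats::median(ens$nulls))
})

test_that("region overlap enrichment handles the degenerate anchors", {
  g <- small_genome()
  q <- g$enhancers_truth[1:10, ]
  ens_self <- region_overlap_enrichment(q, q, g$layout, g$genes,
                                        n_sets = 5, seed = 2)
  expect_equal(ens_self$observed, 1)
  other <- dplyr::mutate(q, chrom = "chrX")
  ens0 <- region_overlap_enrichment(q, other, g$layout, g$genes,
                                    n_sets = 5, seed = 2)
  expect_equal(ens0$observed, 0)
})

test_that("uniformly placed reference regions put the observed overlap inside the null", {
  g <- small_genome()
  q <- g$enhancers_truth
  ref <- withr::with_seed(33, {
    st <- sort(sample(0:(3e6 - 5000), 300))
    tibble::tibble(chrom = "chr1", start = st, end = st + 5000)
  })
  ens <- region_overlap_enrichment(q, ref, g$layout, g$genes,
                                   n_sets = 40, seed = 34)
  spread <- max(stats::sd(ens$nulls), 0.02)
  expect_lt(abs(ens$observed - mean(ens$nulls)), 4 * spread + 0.05)
})

test_that("null ensembles expose tidy, glance and autoplot views", {
  ens <- enhancertx:::new_null_ensemble(5, c(1, 2, 3, 6), 1, "toy stat")
  expect_equal(ens$p, (1 + 1) / 5)
  td <- tidy(ens)
  expect_equal(nrow(td), 4)
  gl <- glance(ens)
  expect_equal(gl$observed, 5)
  expect_s3_class(autoplot(ens), "ggplot")
})
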