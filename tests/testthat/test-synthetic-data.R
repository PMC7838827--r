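# The synthetic data generator: determinism, placement constraints, and the
# statistical structure the downstream analysis assumes.

test_that("genome generation is deterministic and respects placement constraints", {
  g1 <- generate_genome(1, 3e6, n_genes = 25, n_enhancer_states = 30, seed = 7)
  g2 <- generate_genome(1, 3e6, n_genes = 25, n_enhancer_states = 30, seed = 7)
  expect_identical(g1, g2)
  g3 <- generate_genome(1, 3e6, n_genes = 25, n_enhancer_states = 30, seed = 8)
  expect_false(identical(g1$genes$start, g3$genes$start))

  expect_equal(nrow(g1$genes), 25)
  expect_equal(nrow(g1$states), 30)
  # genes do not overlap
  gs <- dplyr::arrange(g1$genes, start)
  expect_true(all(gs$start[-1] >= gs$end[-nrow(gs)]))
  # every enhancer state is >= 1 kbp from every protein-coding TSS
  gtss <- tss(g1$genes)
  for (i in seq_len(nrow(g1$states))) {
    d <- ifelse(g1$states$chrom[i] == g1$genes$chrom,
                pmax(gtss - g1$states$end[i], g1$states$start[i] - gtss), Inf)
    expect_true(all(d >= 1000))
  }
  # mandatory seed
  expect_error(generate_genome(1, 1e6, 5, 5), "seed")
  # impossible placement names the constraint
  expect_error(generate_genome(1, 1e6, n_genes = 200, n_enhancer_states = 5, seed = 1),
               "cannot place")
})

test_that("frac_specific controls one-hot vs ubiquitous enhancer activity", {
  g <- small_genome()
  tr1 <- generate_programs(g, n_cell_lines = 5, frac_specific = 1, seed = 2)
  expect_true(all(rowSums(tr1$enhancer_activity > 0) == 1))
  tr0 <- generate_programs(g, n_cell_lines = 5, frac_specific = 0, seed = 2)
  expect_true(all(rowSums(tr0$enhancer_activity > 0) == ncol(tr0$enhancer_activity)))
  expect_error(generate_programs(g, 5, frac_specific = 1.2, seed = 1), "frac_specific")
  expect_error(generate_programs(g, n_cell_lines = 1, frac_specific = 0, seed = 1),
               "n_cell_lines")
})

test_that("linked enhancer and gene activity are strongly correlated at high coupling", {
  tr <- big_truth()
  expect_gte(nrow(tr$ep_links), 500)
  rs <- purrr::map_dbl(seq_len(nrow(tr$ep_links)), function(k) {
    e <- tr$enhancer_activity[tr$ep_links$enhancer_id[k], ]
    p <- tr$gene_activity[tr$ep_links$gene_id[k], ]
    if (sd(e) == 0 || sd(p) == 0) return(NA_real_)
    cor(e, p)
  })
  expect_gt(mean(rs, na.rm = TRUE), 0.6)
})

test_that("background-only coverage totals follow the Poisson expectation", {
  g <- generate_genome(1, 1e6, n_genes = 5, n_enhancer_states = 5, seed = 3)
  tr <- generate_programs(g, n_cell_lines = 2, frac_specific = 0, seed = 4,
                          dispersion = 0)
  tr$gene_activity[] <- 0
  tr$enhancer_activity[] <- 0
  tr$depth_factor[] <- 1
  cov <- simulate_coverage(g, tr, seed = 5, samples = tr$samples$sample[1],
                           background = 0.05)
  total <- sum(unlist(cov[[1]]$plus)) + sum(unlist(cov[[1]]$minus))
  lambda <- 0.05 * 2 * (1e6 / 200)      # both strands
  expect_lt(abs(total - lambda), 3 * sqrt(lambda))
})

test_that("bin means match the Poisson-log-normal marginal lambda*exp(sigma^2/2)", {
  g <- generate_genome(1, 2e6, n_genes = 3, n_enhancer_states = 3, seed = 6,
                       gene_length_range = c(30000, 40000))
  sigma <- 0.4
  tr <- generate_programs(g, n_cell_lines = 2, frac_specific = 0, seed = 7,
                          dispersion = sigma)
  tr$depth_factor[] <- 1
  act <- 10
  tr$gene_activity[] <- act
  tr$enhancer_activity[] <- 0
  cov <- simulate_coverage(g, tr, seed = 8, samples = tr$samples$sample[1],
                           background = 0)
  # interior gene-body bins on the sense strand carry rate `act`
  gene <- g$genes[1, ]
  idx <- (gene$start / 200 + 3):(gene$end / 200 - 2)
  vec <- if (gene$strand == "+") cov[[1]]$plus$chr1 else cov[[1]]$minus$chr1
  bins <- vec[idx]
  expected <- act * exp(sigma^2 / 2)
  se <- sd(bins) / sqrt(length(bins))
  expect_lt(abs(mean(bins) - expected), 4 * se)
})

test_that("doubling a sample's depth factor doubles its expected total count", {
  g <- generate_genome(1, 1e6, n_genes = 8, n_enhancer_states = 8, seed = 9)
  tr <- generate_programs(g, n_cell_lines = 2, frac_specific = 0, seed = 10,
                          dispersion = 0.1)
  s1 <- tr$samples$sample[1]; s2 <- tr$samples$sample[2]
  tr$depth_factor[s1] <- 2; tr$depth_factor[s2] <- 1
  ratios <- purrr::map_dbl(1:10, function(k) {
    cov <- simulate_coverage(g, tr, seed = 100 + k, samples = c(s1, s2))
    tot <- function(cv) sum(unlist(cv$plus)) + sum(unlist(cv$minus))
    tot(cov[[s1]]) / tot(cov[[s2]])
  })
  expect_lt(abs(mean(ratios) - 2), 0.2)
})

test_that("zero-activity truth with zero background yields all-zero coverage", {
  g <- generate_genome(1, 1e6, n_genes = 5, n_enhancer_states = 5, seed = 11)
  tr <- generate_programs(g, n_cell_lines = 2, frac_specific = 0, seed = 12)
  tr$gene_activity[] <- 0
  tr$enhancer_activity[] <- 0
  cov <- simulate_coverage(g, tr, seed = 13, samples = tr$samples$sample[1],
                           background = 0)
  expect_true(all(unlist(cov[[1]]$plus) == 0))
  expect_true(all(unlist(cov[[1]]$minus) == 0))
})

test_that("every planted E-P link is spanned by a high-scoring interaction", {
  g <- small_genome()
  tr <- small_truth()
  anc <- simulate_ancillary(g, tr, seed = 14)
  gtss <- setNames(tss(g$genes), g$genes$gene_id)
  for (k in seq_len(nrow(tr$ep_links))) {
    e <- g$enhancers_truth[match(tr$ep_links$enhancer_id[k],
                                 g$enhancers_truth$enhancer_id), ]
    t0 <- gtss[tr$ep_links$gene_id[k]]
    hit <- anc$interactions$score >= 3 &
      anc$interactions$bait_start <= t0 & anc$interactions$bait_end > t0 &
      anc$interactions$hit_start < e$end & anc$interactions$hit_end > e$start
    expect_true(any(hit))
  }
})

test_that("unit enrichment factor gives equal trait and background in-enhancer rates", {
  g <- small_genome()
  tr <- small_truth()
  anc <- simulate_ancillary(g, tr, seed = 15, enrichment = 1,
                            n_trait = 2000, n_background = 8000)
  in_enh <- function(snps) {
    mean(purrr::map_lgl(seq_len(nrow(snps)), function(i) {
      any(g$enhancers_truth$chrom == snps$chrom[i] &
            g$enhancers_truth$start <= snps$pos[i] &
            g$enhancers_truth$end > snps$pos[i])
    }))
  }
  tf <- in_enh(dplyr::filter(anc$snps, set == "trait"))
  bf <- in_enh(dplyr::filter(anc$snps, set == "background"))
  # binomial sampling error bound
  se <- sqrt(tf * (1 - tf) / 2000 + bf * (1 - bf) / 8000 + 1e-8)
  expect_lt(abs(tf - bf), 4 * se + 0.005)
})
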