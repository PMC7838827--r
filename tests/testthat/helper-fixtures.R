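# Shared fixtures and independent oracles. Expensive objects are computed
# once per test run and cached in this environment.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small synthetic genome + truth shared by several files.
small_genome <- function() cached("small_genome", {
  generate_genome(1, 3e6, n_genes = 25, n_enhancer_states = 30, seed = 7)
})

small_truth <- function() cached("small_truth", {
  generate_programs(small_genome(), n_cell_lines = 4, frac_specific = 0, seed = 11)
})

# A noise-free single-sample coverage over the small genome.
small_noisefree <- function() cached("small_noisefree", {
  simulate_coverage(small_genome(), small_truth(),
                    samples = small_truth()$samples$sample[1],
                    background = 0, noise = FALSE)[[1]]
})

# Larger genome/truth for the coupling and pairing-recall checks (>= 500
# planted E-P links over 14 cell lines).
big_genome <- function() cached("big_genome", {
  generate_genome(2, 20e6, n_genes = 800, n_enhancer_states = 1000, seed = 42)
})

big_truth <- function() cached("big_truth", {
  generate_programs(big_genome(), n_cell_lines = 14, frac_specific = 0.37,
                    coupling = 0.9, frac_linked = 1, seed = 43)
})

# 10-Mbp genome used for noise-free truth recovery and the interaction
# calibration runs.
recovery_genome <- function() cached("recovery_genome", {
  generate_genome(1, 10e6, n_genes = 100, n_enhancer_states = 150, seed = 17)
})

recovery_truth <- function() cached("recovery_truth", {
  generate_programs(recovery_genome(), n_cell_lines = 2, frac_specific = 0,
                    seed = 18)
})

# One complete pipeline run at reduced scale, reused across files.
demo_run <- function() cached("demo_run", {
  cfg <- pipeline_config(seed = 5, chrom_length_bp = 2e6, n_genes = 20,
                         n_enhancer_states = 25, n_cell_lines = 4,
                         n_ep_null_sets = 20, n_snp_null_sets = 50,
                         hmm_fit_bins = 8000, hmm_max_iter = 25)
  suppressWarnings(run_pipeline(cfg))
})

# Build a binned_coverage with explicit per-bin counts on one chromosome.
toy_coverage <- function(plus, minus = rep(0L, length(plus)), bin_width = 200L,
                         chrom = "chr1", sample_id = "toy") {
  layout <- genome_layout(tibble::tibble(chrom = chrom,
                                         length = length(plus) * bin_width),
                          bin_width = bin_width)
  binned_coverage(sample_id, layout,
                  plus = stats::setNames(list(as.integer(plus)), chrom),
                  minus = stats::setNames(list(as.integer(minus)), chrom))
}

# --- independent oracles ------------------------------------------------

# Exhaustive Viterbi: enumerate all 2^T state paths.
brute_force_viterbi <- function(x, model) {
  gh <- pracma::gaussHermite(model$n_nodes)
  logB <- cbind(
    enhancertx:::pln_logdens(x, model$emission$meanlog[1], model$emission$sdlog[1], gh),
    enhancertx:::pln_logdens(x, model$emission$meanlog[2], model$emission$sdlog[2], gh))
  Tn <- length(x)
  best <- NULL
  best_lp <- -Inf
  grid <- expand.grid(rep(list(1:2), Tn))
  for (i in seq_len(nrow(grid))) {
    path <- as.integer(unlist(grid[i, ]))
    lp <- log(model$init[path[1]]) + logB[1, path[1]]
    if (Tn > 1) for (t in 2:Tn) {
      lp <- lp + log(model$transition[path[t - 1], path[t]]) + logB[t, path[t]]
    }
    # strict improvement keeps the earliest (lexicographically smallest)
    # maximizer, which is the all-ties-to-state-1 path
    if (lp > best_lp + 1e-12) { best_lp <- lp; best <- path }
  }
  best
}

# Direct evaluations of the two specificity scores, written independently
# of the package implementation.
oracle_entropy_score <- function(x) {
  p <- x / sum(x)
  p <- p[p > 0]
  H <- -sum(p * log(p)) / log(2)
  1 - H / (log(length(x)) / log(2))
}

oracle_js_score <- function(t, c) {
  H <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  p1 <- t / sum(t)
  p2 <- replace(numeric(length(t)), c, 1)
  js <- H((p1 + p2) / 2) - (H(p1) + H(p2)) / 2
  1 - sqrt(max(js, 0))
}

# Reciprocal-overlap matching of two interval sets.
reciprocal_match <- function(a, b, min_frac = 0.9) {
  ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start + 1, a$end))
  gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start + 1, b$end))
  h <- GenomicRanges::findOverlaps(ga, gb)
  ov <- GenomicRanges::width(GenomicRanges::pintersect(
    ga[S4Vectors::queryHits(h)], gb[S4Vectors::subjectHits(h)]))
  frac <- ov / pmax(GenomicRanges::width(ga[S4Vectors::queryHits(h)]),
                    GenomicRanges::width(gb[S4Vectors::subjectHits(h)]))
  list(
    a_matched = length(unique(S4Vectors::queryHits(h)[frac >= min_frac])) / nrow(a),
    b_matched = length(unique(S4Vectors::subjectHits(h)[frac >= min_frac])) / nrow(b)
  )
}

# Activity vector correlated with `a` at exactly `r` on the log2(x+1) scale.
make_correlated_activity <- function(a, r, seed = 1) {
  withr::with_seed(seed, {
    z1 <- scale(log2(a + 1))[, 1]
    raw <- stats::rnorm(length(a))
    z2 <- scale(stats::residuals(stats::lm(raw ~ z1)))[, 1]  # exactly orthogonal
    y <- r * z1 + sqrt(1 - r^2) * z2
    2^(6 + y) - 1
  })
}
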