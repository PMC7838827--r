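# HMM fitting, Viterbi decoding, TU merging and boundary refinement.

test_that("EM log-likelihood is non-decreasing and converges on planted data", {
  set.seed(7)
  x <- as.integer(c(rpois(400, 0.1), rpois(100, 20), rpois(400, 0.1),
                    rpois(150, 20), rpois(400, 0.1)))
  m <- fit_hmm(x, seed = 1)
  expect_true(all(diff(m$loglik_trace) >= -1e-6))
  expect_true(m$converged)
  expect_true(m$emission$mean[2] > m$emission$mean[1])
  expect_equal(rowSums(m$transition), c(1, 1), tolerance = 1e-9)
})

test_that("an infinite tolerance returns the initialization after one iteration", {
  set.seed(8)
  x <- as.integer(c(rpois(200, 0.1), rpois(100, 15)))
  m <- fit_hmm(x, tol = Inf, seed = 1)
  expect_equal(m$n_iter, 1L)
  expect_length(m$loglik_trace, 1)
  # initialization values survive untouched
  expect_equal(m$emission$sdlog, c(0.5, 0.5))
})

test_that("all-zero coverage is rejected with a skip instruction", {
  expect_error(fit_hmm(integer(200), seed = 1), "skip segmentation")
  expect_error(fit_hmm(integer(50), seed = 1), "100 bins")
})

test_that("fitted emission means recover the generating state means within 15%", {
  set.seed(9)
  # 50k bins from a known 2-state chain with emission means 0.1 and 20
  Tn <- 50000
  A <- matrix(c(0.98, 0.02, 0.05, 0.95), 2, 2, byrow = TRUE)
  states <- integer(Tn)
  states[1] <- 1L
  r <- runif(Tn)
  for (t in 2:Tn) states[t] <- if (r[t] < A[states[t - 1], 1]) 1L else 2L
  sigma <- 0.3
  lam <- ifelse(states == 1, 0.1, 20) * exp(sigma * rnorm(Tn) - sigma^2 / 2)
  x <- rpois(Tn, lam)
  m <- fit_hmm(x, seed = 2)
  expect_lt(abs(m$emission$mean[1] - 0.1) / 0.1, 0.15)
  expect_lt(abs(m$emission$mean[2] - 20) / 20, 0.15)
})

test_that("Viterbi decoding equals exhaustive path enumeration on short toys", {
  set.seed(10)
  for (rep in 1:8) {
    Tn <- sample(6:12, 1)
    model <- structure(list(
      transition = {
        a <- runif(1, 0.7, 0.99); b <- runif(1, 0.7, 0.99)
        matrix(c(a, 1 - a, 1 - b, b), 2, 2, byrow = TRUE)
      },
      init = { p <- runif(1, 0.2, 0.8); c(p, 1 - p) },
      emission = tibble::tibble(state = c("untranscribed", "transcribed"),
                                meanlog = c(log(runif(1, 0.05, 0.5)),
                                            log(runif(1, 5, 30))),
                                sdlog = runif(2, 0.1, 0.6)),
      n_nodes = 20L), class = "pln_hmm")
    x <- as.integer(rpois(Tn, sample(c(0.2, 10), Tn, replace = TRUE)))
    expect_equal(enhancertx:::viterbi_path(x, model), brute_force_viterbi(x, model))
  }
})

test_that("Viterbi ties resolve to the untranscribed state", {
  model <- structure(list(
    transition = matrix(0.5, 2, 2),
    init = c(0.5, 0.5),
    emission = tibble::tibble(state = c("untranscribed", "transcribed"),
                              meanlog = c(log(2), log(2)), sdlog = c(0.3, 0.3)),
    n_nodes = 20L), class = "pln_hmm")
  x <- as.integer(c(1, 2, 3, 2, 1))
  expect_equal(enhancertx:::viterbi_path(x, model), rep(1L, 5))
})

test_that("a planted block decodes to exactly one TU within one bin", {
  cov <- toy_coverage(plus = c(rep(0L, 40), rep(12L, 20), rep(0L, 40)))
  m <- fit_hmm(c(rep(0L, 200), rep(12L, 60), rep(0L, 100)), seed = 3)
  tus <- decode_tus(cov, m)
  expect_equal(nrow(tus), 1)
  expect_lte(abs(tus$start - 40 * 200), 200)
  expect_lte(abs(tus$end - 60 * 200), 200)
  # all-background coverage gives zero TUs
  cov0 <- toy_coverage(plus = rep(0L, 120))
  expect_equal(nrow(decode_tus(cov0, m)), 0)
})

test_that("decoding is invariant to a common scale on counts and emission means", {
  set.seed(11)
  cov <- toy_coverage(plus = as.integer(c(rpois(50, 0.2), rpois(30, 8), rpois(50, 0.2))))
  m <- fit_hmm(as.integer(c(rpois(300, 0.2), rpois(100, 8))), seed = 4)
  tus1 <- decode_tus(cov, m)
  cov10 <- cov
  cov10$plus$chr1 <- cov$plus$chr1 * 10L
  m10 <- m
  m10$emission$meanlog <- m$emission$meanlog + log(10)
  tus2 <- decode_tus(cov10, m10)
  expect_equal(tus1[c("start", "end", "strand")], tus2[c("start", "end", "strand")])
})

test_that("TUs stay disjoint per strand after merging", {
  r <- demo_run()
  for (line in names(r$per_line)) {
    tus <- r$per_line[[line]]$tus
    for (s in c("+", "-")) {
      g <- dplyr::arrange(dplyr::filter(tus, strand == s), chrom, start)
      if (nrow(g) > 1) {
        same <- g$chrom[-1] == g$chrom[-nrow(g)]
        expect_true(all(g$start[-1][same] >= g$end[-nrow(g)][same]))
      }
    }
  }
})

test_that("gap merging bridges one bin, inclusively and transitively", {
  tus <- tibble::tibble(
    chrom = "chr1",
    start = c(1000, 2200, 5000, 8000, 9200, 10400),
    end = c(2000, 3000, 7600, 9000, 10200, 11000),
    strand = "+",
    class = c("intergenic", "intergenic", "intergenic", "intergenic",
              "intergenic", "intergenic"),
    tu_id = paste0("TU", 1:6))
  out <- merge_gaps(tus, max_gap_bp = 200)
  # 1000-2000 and 2200-3000: gap exactly 200 -> merged
  expect_true(any(out$start == 1000 & out$end == 3000))
  # 3000 -> 5000 gap 2000 -> separate
  expect_true(any(out$start == 5000 & out$end == 7600))
  # chain of three 200-bp gaps collapses to one TU
  expect_true(any(out$start == 8000 & out$end == 11000))
  # mRNAs are left untouched under the noncoding scope
  tus$class[1] <- "mRNA"
  out2 <- merge_gaps(tus, max_gap_bp = 200)
  expect_true(any(out2$start == 1000 & out2$end == 2000))
})

test_that("boundary refinement finds an exact step and leaves flat coverage alone", {
  # per-bp coverage with a step 0 -> 10 at bp 1234, TU boundary initially 1200
  vec <- c(rep(0, 1234), rep(10, 2000 - 1234))
  bp_cov <- list(plus = list(chr1 = vec), minus = list(chr1 = rep(0, 2000)))
  tu <- tibble::tibble(chrom = "chr1", start = 1200, end = 1800, strand = "+")
  out <- refine_boundaries(tu, bp_cov)
  expect_equal(out$start, 1234)

  flat <- list(plus = list(chr1 = rep(5, 2000)), minus = list(chr1 = rep(0, 2000)))
  out2 <- refine_boundaries(tu, flat)
  expect_equal(out2$start, 1200)
  expect_equal(out2$end, 1800)

  # a boundary never moves farther than the refinement window
  set.seed(12)
  noisy <- list(plus = list(chr1 = rpois(2000, 3)), minus = list(chr1 = rep(0, 2000)))
  out3 <- refine_boundaries(tu, noisy, window_bp = 200)
  expect_lte(abs(out3$start - 1200), 400)
  expect_lte(abs(out3$end - 1800), 400)
})
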