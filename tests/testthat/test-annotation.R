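# TU classification, eRNA calling, divergent pairing, enhancer-region
# construction, union merge and quantification.

toy_gene <- function(start = 10000, end = 40000, strand = "+", id = "g1") {
  tibble::tibble(chrom = "chr1", start = start, end = end, strand = strand,
                 gene_id = id, biotype = "protein_coding")
}

toy_exons <- function(genes) {
  dplyr::select(genes, chrom, start, end, strand, gene_id)
}

test_that("TSS position relative to the sense TSS drives ncRNA classes", {
  g <- toy_gene()                        # + gene, TSS 10,000
  ex <- toy_exons(g)
  tus <- tibble::tibble(
    chrom = "chr1",
    start = c(8400, 9600, 11000),
    end = c(9500, 10600, 12000),
    strand = "-")
  out <- classify_tus(tus, g, ex)
  # minus TU TSS = end: 9,500 (500 bp upstream) / 10,600 (600 downstream) /
  # 12,000 (2 kbp downstream, overlapping the gene)
  expect_equal(out$class, c("uaRNA", "conRNA", "asRNA"))
  expect_equal(out$host_gene, rep("g1", 3))
})

test_that("mRNA needs 25% gene coverage on the same strand plus an exon hit", {
  g <- toy_gene(10000, 30000)
  # exons only in the first 40% of the gene
  ex <- tibble::tibble(chrom = "chr1", start = 10000, end = 18000,
                       strand = "+", gene_id = "g1")
  tu_cov30_no_exon <- tibble::tibble(chrom = "chr1", start = 22000, end = 28000,
                                     strand = "+")
  expect_equal(classify_tus(tu_cov30_no_exon, g, ex)$class, "intergenic")
  tu_cov30_exon <- tibble::tibble(chrom = "chr1", start = 12000, end = 18000,
                                  strand = "+")
  expect_equal(classify_tus(tu_cov30_exon, g, ex)$class, "mRNA")
  tu_cov20 <- tibble::tibble(chrom = "chr1", start = 12000, end = 16000,
                             strand = "+")
  expect_equal(classify_tus(tu_cov20, g, ex)$class, "intergenic")
})

test_that("eRNA calling applies the TSS window against enhancer states", {
  states <- tibble::tibble(chrom = "chr1", start = 5000, end = 6000)
  g <- toy_gene(100000, 130000)
  mk_tu <- function(tss) tibble::tibble(chrom = "chr1", start = tss,
                                        end = tss + 2000, strand = "+",
                                        tss = tss, class = "intergenic",
                                        host_gene = NA_character_,
                                        tu_id = "TUx")
  # TSS 400 bp right of the state edge: within the +-500 window
  expect_equal(nrow(call_ernas(mk_tu(6400), states, g)), 1)
  # 600 bp away: out
  expect_equal(nrow(call_ernas(mk_tu(6600), states, g)), 0)
  # exclusion list drops overlapping TUs
  excl <- tibble::tibble(chrom = "chr1", start = 6000, end = 7000)
  expect_equal(nrow(call_ernas(mk_tu(6400), states, g, exclusions = excl)), 0)
})

test_that("long antisense eRNAs are truncated at host TSS + 1 kbp", {
  g <- toy_gene(10000, 40000, "+")       # TSS 10,000, promoter 9,000-11,000
  states <- tibble::tibble(chrom = "chr1", start = 19500, end = 20500)
  # asRNA on minus strand, TSS 20,000, running left across the promoter
  tu <- tibble::tibble(chrom = "chr1", start = 9500, end = 20000, strand = "-",
                       tss = 20000, class = "asRNA", host_gene = "g1",
                       tu_id = "TUa")
  out <- call_ernas(tu, states, g)
  expect_equal(out$start, 11000)         # 1 kbp downstream of the + TSS
  expect_equal(out$end, 20000)
})

test_that("readthrough antisense eRNAs need 2-fold signal over the upstream TU end", {
  # + strand: mRNA [0, 10,000) then an antisense eRNA TU [12,000, 13,000)
  plus <- rep(0L, 100)
  plus[46:50] <- 5L                      # last 1 kbp of the mRNA: 25 counts
  plus[61:65] <- 8L                      # eRNA bins: 40 counts -> FPK 40
  cov <- toy_coverage(plus = plus)
  tus <- tibble::tibble(
    chrom = "chr1", start = c(0, 12000), end = c(10000, 13000), strand = "+",
    tss = c(0, 12000), class = c("mRNA", "asRNA"), host_gene = c("g1", "g2"),
    tu_id = c("TU1", "TU2"))
  ernas <- dplyr::mutate(tus[2, ], erna_id = "eRNA1", kind = "antisense")
  # upstream-end FPK 25, eRNA FPK 40 < 2 x 25 -> dropped
  expect_equal(nrow(filter_antisense(ernas, tus, cov, 1)), 0)
  # eRNA FPK 60 >= 50 -> kept
  plus2 <- plus; plus2[61:65] <- 12L
  expect_equal(nrow(filter_antisense(ernas, tus, toy_coverage(plus = plus2), 1)), 1)
  # beyond the 5-kbp chain: kept unconditionally
  tus_far <- tus; tus_far$start[2] <- 16000; tus_far$end[2] <- 17000
  ernas_far <- dplyr::mutate(tus_far[2, ], erna_id = "eRNA1", kind = "antisense")
  expect_equal(nrow(filter_antisense(ernas_far, tus_far, cov, 1)), 1)
})

test_that("divergent pairing honors the 750-bp gap bound and geometry", {
  mk <- function(start, end, strand, id, class = "intergenic") {
    tibble::tibble(chrom = "chr1", start = start, end = end, strand = strand,
                   tss = ifelse(strand == "-", end, start), class = class,
                   host_gene = NA_character_, tu_id = id)
  }
  erna_p <- dplyr::mutate(mk(5750, 7750, "+", "e1"), erna_id = "e1",
                          kind = "intergenic")
  # divergent, gap exactly 750 -> paired
  tu_m <- mk(3000, 5000, "-", "m1")
  out <- pair_bidirectional(erna_p, dplyr::bind_rows(tu_m, dplyr::select(erna_p, -erna_id, -kind)))
  expect_equal(nrow(out), 1)
  expect_equal(out$gap, 750)
  # gap 800 -> unpaired
  erna_far <- dplyr::mutate(erna_p, start = 5800, end = 7800, tss = 5800)
  expect_equal(nrow(pair_bidirectional(erna_far, tu_m)), 0)
  # convergent configuration never pairs regardless of distance
  tu_conv <- mk(8000, 10000, "-", "c1")  # minus TSS 10,000 right of the + TU
  expect_equal(nrow(pair_bidirectional(erna_p, tu_conv)), 0)
  # overlapping divergent TSSs (negative gap) do pair
  tu_ovl <- mk(4000, 6000, "-", "o1")    # minus TSS 6,000 > plus TSS 5,750
  out_ovl <- pair_bidirectional(erna_p, tu_ovl)
  expect_equal(nrow(out_ovl), 1)
  expect_equal(out_ovl$gap, -250)
})

test_that("enhancer-region construction matches the published geometry", {
  pairs <- tibble::tibble(chrom = "chr1", erna_id = "e1", partner_id = "e2",
                          tss_plus = 5400, tss_minus = 5000, gap = 400)
  enh <- define_enhancers(pairs)
  expect_equal(enh$start, 4500)
  expect_equal(enh$end, 5900)
  expect_equal(enh$end - enh$start, 1400)

  anti <- tibble::tibble(chrom = "chr1", start = 28000, end = 30000,
                         strand = "-", tss = 30000, class = "asRNA",
                         host_gene = "g1", tu_id = "t", erna_id = "a1",
                         kind = "antisense")
  enh2 <- define_enhancers(pairs[0, ], anti)
  expect_equal(enh2$start, 29500)
  expect_equal(enh2$end, 30750)
  # plus-strand antisense eRNA mirrors the construction
  anti_p <- dplyr::mutate(anti, strand = "+", tss = 28000)
  enh3 <- define_enhancers(pairs[0, ], anti_p)
  expect_equal(c(enh3$start, enh3$end), c(27250, 28500))
  # every intragenic region is exactly 1,250 bp
  expect_true(all((enh2$end - enh2$start) == 1250))
  expect_true(all((enh3$end - enh3$start) == 1250))
})

test_that("cross-cell-line merging is transitive and keeps provenance", {
  a <- tibble::tibble(chrom = "chr1", start = 1000, end = 2000, kind = "intergenic")
  b <- tibble::tibble(chrom = "chr1", start = c(1000, 5000), end = c(2000, 6000),
                      kind = "intergenic")
  m <- merge_across_cell_lines(list(L1 = a, L2 = b))
  expect_equal(nrow(m), 2)
  expect_equal(m$sources[m$start == 1000], "L1,L2")
  expect_equal(m$n_sources[m$start == 1000], 2L)
  # chain merge: A overlaps B, B overlaps C, A and C disjoint
  chain <- list(
    L1 = tibble::tibble(chrom = "chr1", start = 1000, end = 2000, kind = "intergenic"),
    L2 = tibble::tibble(chrom = "chr1", start = 1500, end = 2500, kind = "intergenic"),
    L3 = tibble::tibble(chrom = "chr1", start = 2400, end = 3000, kind = "intergenic"))
  mc <- merge_across_cell_lines(chain)
  expect_equal(nrow(mc), 1)
  expect_equal(mc$sources, "L1,L2,L3")
})

test_that("enhancer quantification applies strand rules and length corrections", {
  # intragenic enhancer width 1,250, eRNA on minus strand, 10 antisense counts
  minus <- rep(0L, 100); minus[3:7] <- 2L
  plus <- rep(0L, 100); plus[3:7] <- 99L          # sense counts must be ignored
  cov <- list(s1 = toy_coverage(plus = plus, minus = minus))
  reg <- tibble::tibble(enhancer_id = "E1", chrom = "chr1", start = 350,
                        end = 1600, kind = "intragenic", erna_strand = "-")
  a <- quantify_enhancers(reg, cov, c(s1 = 1))
  expect_equal(unname(a$fpk[1, 1]), 10 / 0.5)      # effective length 500 bp

  # intergenic width 2,000 with 15 + 25 counts over both strands
  plus2 <- rep(0L, 100); plus2[11:15] <- 3L
  minus2 <- rep(0L, 100); minus2[11:15] <- 5L
  cov2 <- list(s1 = toy_coverage(plus = plus2, minus = minus2))
  reg2 <- tibble::tibble(enhancer_id = "E2", chrom = "chr1", start = 2000,
                         end = 4000, kind = "intergenic", erna_strand = NA_character_)
  a2 <- quantify_enhancers(reg2, cov2, c(s1 = 1))
  expect_equal(unname(a2$fpk[1, 1]), 40 / 2)
  # zero counts give FPK 0
  reg3 <- dplyr::mutate(reg2, start = 10000, end = 12000)
  expect_equal(unname(quantify_enhancers(reg3, cov2, c(s1 = 1))$fpk[1, 1]), 0)
})

test_that("eRNA classes stay mutually exclusive and promoter-distant on a full run", {
  r <- demo_run()
  for (line in names(r$per_line)) {
    tus <- r$per_line[[line]]$tus
    expect_true(all(tus$class %in% c("mRNA", "uaRNA", "conRNA", "asRNA",
                                     "intergenic", "unclassified")))
    ernas <- r$per_line[[line]]$ernas
    if (nrow(ernas) == 0) next
    gtss <- tss(r$genome$genes)
    for (i in seq_len(nrow(ernas))) {
      d <- abs(gtss[r$genome$genes$chrom == ernas$chrom[i]] - ernas$tss[i])
      expect_gte(min(d), 1000)
    }
  }
})
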