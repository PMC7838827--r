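# Ancillary synthetic inputs: promoter-capture interaction tables, SNP
# catalogs, and co-activator peak signal for super-enhancer stitching.

#' Simulate interaction, SNP and peak-signal tables
#'
#' Builds the three optional inputs downstream modules consume:
#' \describe{
#'   \item{interactions}{Fixed-size restriction-fragment stand-ins (default
#'     4 kbp tiles). Every planted E-P link gets one interaction whose bait
#'     tile covers the gene TSS and hit tile covers the enhancer midpoint,
#'     with score >= 3; random decoy tile pairs carry scores < 3.}
#'   \item{snps}{`n_trait` trait SNPs placed inside enhancer regions at
#'     `enrichment` times the background in-enhancer probability, plus
#'     `n_background` uniformly placed background SNPs; both carry matching
#'     covariates (`maf`, `gene_density`, `dist_nearest_gene`).}
#'   \item{peaks}{One peak per enhancer region with signal proportional to
#'     summed enhancer activity; a `tail_frac` fraction gets a heavy-tail
#'     multiplier so super-enhancers can form.}
#' }
#'
#' @param genome A [generate_genome()] result.
#' @param truth A [generate_programs()] result.
#' @param seed Mandatory RNG seed.
#' @param frag_size Interaction fragment (tile) size, bp.
#' @param n_decoys Number of decoy interactions.
#' @param n_trait,n_background SNP set sizes.
#' @param enrichment Trait-SNP in-enhancer enrichment factor over background.
#' @param tail_frac Fraction of peaks receiving the heavy-tail multiplier.
#' @param tail_scale Log-normal sdlog of the heavy-tail multiplier.
#' @return A list with tibbles `interactions`, `snps`, `peaks`.
#' @export
simulate_ancillary <- function(genome, truth, seed, frag_size = 4000L,
                               n_decoys = 300L, n_trait = 500L,
                               n_background = 5000L, enrichment = 3,
                               tail_frac = 0.1, tail_scale = 2) {
  if (missing(seed)) abort("seed is mandatory")
  layout <- genome$layout
  genes <- genome$genes
  enh <- genome$enhancers_truth
  tile <- function(pos) floor(pos / frag_size) * frag_size
  with_seed(seed, {
    # -- interactions ------------------------------------------------------
    links <- truth$ep_links
    real <- list_rbind(map(seq_len(nrow(links)), function(k) {
      g <- genes[match(links$gene_id[k], genes$gene_id), ]
      e <- enh[match(links$enhancer_id[k], enh$enhancer_id), ]
      b0 <- tile(tss(g))
      h0 <- tile((e$start + e$end) / 2)
      tibble(bait_chrom = g$chrom, bait_start = b0, bait_end = b0 + frag_size,
             hit_chrom = e$chrom, hit_start = h0, hit_end = h0 + frag_size,
             score = runif(1, 3, 10))
    }))
    decoys <- list_rbind(map(seq_len(n_decoys), function(k) {
      ch <- sample(layout$chromosomes$chrom, 1)
      len <- layout$chromosomes$length[match(ch, layout$chromosomes$chrom)]
      b0 <- tile(runif(1, 0, len - frag_size))
      h0 <- tile(min(max(0, b0 + sample(c(-1, 1), 1) * runif(1, 2 * frag_size, 5e5)),
                     len - frag_size))
      tibble(bait_chrom = ch, bait_start = b0, bait_end = b0 + frag_size,
             hit_chrom = ch, hit_start = h0, hit_end = h0 + frag_size,
             score = runif(1, 0.1, 2.9))
    }))
    interactions <- bind_rows(real, decoys)

    # -- SNPs --------------------------------------------------------------
    enh_bp <- sum(enh$end - enh$start)
    genome_bp <- sum(layout$chromosomes$length)
    p_in <- min(1, enrichment * enh_bp / genome_bp)
    place_uniform <- function(n) {
      ch <- sample(layout$chromosomes$chrom, n, replace = TRUE,
                   prob = layout$chromosomes$length)
      pos <- floor(runif(n, 0, layout$chromosomes$length[
        match(ch, layout$chromosomes$chrom)]))
      tibble(chrom = ch, pos = pos)
    }
    place_in_enh <- function(n) {
      i <- sample.int(nrow(enh), n, replace = TRUE,
                      prob = enh$end - enh$start)
      tibble(chrom = enh$chrom[i],
             pos = floor(runif(n, enh$start[i], enh$end[i])))
    }
    counter <- region_counter(enh)
    inside_enh <- function(snps) counter(snps$chrom, snps$pos)
    place_outside <- function(n) {
      out <- place_uniform(n)
      repeat {                               # rejection-sample out of enhancers
        bad <- inside_enh(out)
        if (!any(bad)) break
        out[bad, ] <- place_uniform(sum(bad))
      }
      out
    }
    n_in <- stats::rbinom(1, n_trait, p_in)
    trait <- bind_rows(place_in_enh(n_in), place_outside(n_trait - n_in))
    backg <- place_uniform(n_background)
    snps <- bind_rows(mutate(trait, set = "trait"),
                      mutate(backg, set = "background"))
    snps$maf <- runif(nrow(snps), 0.01, 0.5)
    snps <- add_snp_covariates(snps, genes)

    # -- peaks -------------------------------------------------------------
    sig <- rowSums(truth$enhancer_activity) * rlnorm(nrow(enh), 0, 0.4)
    heavy <- runif(nrow(enh)) < tail_frac
    sig[heavy] <- sig[heavy] * rlnorm(sum(heavy), tail_scale, tail_scale)
    peaks <- tibble(chrom = enh$chrom, start = enh$start, end = enh$end,
                    peak_id = paste0("peak_", enh$enhancer_id),
                    strand = ".", signal = sig)
  })
  list(interactions = interactions, snps = snps, peaks = peaks)
}

# Positional covariates used for matched-null SNP sampling (vectorized via
# sorted-TSS binary search per chromosome).
add_snp_covariates <- function(snps, genes, density_window = 100000) {
  gtss <- tss(genes)
  snps$gene_density <- 0L
  snps$dist_nearest_gene <- NA_real_
  for (ch in unique(snps$chrom)) {
    ts <- sort(gtss[genes$chrom == ch])
    sel <- which(snps$chrom == ch)
    if (length(ts) == 0 || length(sel) == 0) next
    pos <- snps$pos[sel]
    lo <- findInterval(pos - density_window - 0.5, ts)
    hi <- findInterval(pos + density_window, ts)
    snps$gene_density[sel] <- hi - lo
    i <- findInterval(pos, ts)
    d_left <- ifelse(i >= 1, pos - ts[pmax(i, 1)], Inf)
    d_right <- ifelse(i < length(ts), ts[pmin(i + 1, length(ts))] - pos, Inf)
    snps$dist_nearest_gene[sel] <- pmin(d_left, d_right)
  }
  snps
}
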