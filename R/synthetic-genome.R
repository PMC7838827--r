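# Synthetic genome generator: a toy genome with protein-coding genes,
# chromatin-state enhancer intervals, and the planted eRNA geometry that the
# coverage simulator transcribes. All planted boundaries snap to bin edges so
# that bin-resolution segmentation can recover the truth exactly on
# noise-free coverage.

snap_bin <- function(x, w) as.integer(round(x / w) * w)

#' Generate a toy genome with genes and enhancer-state intervals
#'
#' Places non-overlapping protein-coding genes (each with two exons) and
#' enhancer-state intervals (intergenic or intragenic) on one or more
#' chromosomes. Every enhancer state is at least 1 kbp away from any
#' protein-coding TSS; placement is deterministic for a fixed seed. Each
#' state also carries its planted eRNA geometry: a divergent eRNA pair
#' (intergenic states, TSS gap `erna_gap`) or a single antisense eRNA
#' (intragenic states).
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length_bp Length of each chromosome (multiple of `bin_width`).
#' @param n_genes,n_enhancer_states Total features to place.
#' @param seed Mandatory RNG seed.
#' @param bin_width Bin width in bp (default 200).
#' @param gene_length_range Gene length range in bp (snapped to bins).
#' @param min_gene_gap Minimal gap between adjacent genes, bp.
#' @param frac_intragenic Fraction of enhancer states placed inside genes.
#' @param state_width Enhancer-state interval width, bp.
#' @param erna_gap TSS gap of the planted divergent eRNA pair, bp (<= 750).
#' @param erna_length_range Planted eRNA length range, bp (snapped to bins).
#' @param state_margin Minimal distance of an intergenic state's eRNA span
#'   from any gene body, bp.
#' @param state_spacing Minimal spacing between intergenic state centers, bp.
#' @return A list of class `synthetic_genome`: `layout` ([genome_layout()]),
#'   `genes`, `exons`, `states`, `ernas_truth`, `enhancers_truth` tibbles.
#' @export
generate_genome <- function(n_chrom = 1L, chrom_length_bp = 10e6,
                            n_genes = 100L, n_enhancer_states = 150L,
                            seed,
                            bin_width = 200L,
                            gene_length_range = c(10000, 40000),
                            min_gene_gap = 20000,
                            frac_intragenic = 0.3,
                            state_width = 1000L,
                            erna_gap = 400L,
                            erna_length_range = c(1600, 2400),
                            state_margin = 3000L,
                            state_spacing = 6000L) {
  if (missing(seed)) abort("seed is mandatory")
  stopifnot(erna_gap <= 750)
  layout <- genome_layout(
    tibble(chrom = paste0("chr", seq_len(n_chrom)),
           length = rep(as.integer(chrom_length_bp), n_chrom)),
    bin_width = bin_width
  )
  with_seed(seed, {
    genes_per_chrom <- diff(round(seq(0, n_genes, length.out = n_chrom + 1)))
    genes <- list_rbind(map(seq_len(n_chrom), function(ci) {
      place_genes(layout$chromosomes$chrom[ci], chrom_length_bp,
                  genes_per_chrom[ci], gene_length_range, min_gene_gap, bin_width)
    }))
    genes$gene_id <- sprintf("gene%04d", seq_len(nrow(genes)))
    genes$biotype <- "protein_coding"
    exons <- make_exons(genes, bin_width)

    n_intra <- round(frac_intragenic * n_enhancer_states)
    n_inter <- n_enhancer_states - n_intra
    states <- bind_rows(
      place_intragenic_states(genes, n_intra, state_width, bin_width),
      place_intergenic_states(layout, genes, n_inter, state_width, bin_width,
                              state_margin + max(erna_length_range), state_spacing)
    )
    states$state_id <- sprintf("state%04d", seq_len(nrow(states)))

    ernas <- plant_ernas(states, genes, bin_width, erna_gap, erna_length_range)
    enhancers <- planted_enhancer_regions(ernas)
  })
  structure(list(layout = layout, genes = genes, exons = exons,
                 states = states, ernas_truth = ernas,
                 enhancers_truth = enhancers),
            class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome> %d gene(s), %d enhancer state(s) (%d intergenic / %d intragenic), %d planted eRNA(s)\n",
    nrow(x$genes), nrow(x$states), sum(x$states$kind == "intergenic"),
    sum(x$states$kind == "intragenic"), nrow(x$ernas_truth)))
  print(x$layout)
  invisible(x)
}

place_genes <- function(chrom, chrom_len, n, length_range, min_gap, w) {
  if (n == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  lens <- snap_bin(runif(n, length_range[1], length_range[2]), w)
  slack <- chrom_len - sum(lens) - (n + 1) * min_gap
  if (slack < 0) {
    abort(sprintf(
      "cannot place %d genes on a %.3g-bp chromosome with min gap %d (need %.3g more bp)",
      n, chrom_len, min_gap, -slack))
  }
  cuts <- sort(runif(n, 0, slack))
  extra <- snap_bin(diff(c(0, cuts)), w)
  starts <- integer(n)
  pos <- 0
  for (i in seq_len(n)) {
    pos <- pos + min_gap + extra[i]
    starts[i] <- snap_bin(pos, w)
    pos <- starts[i] + lens[i]
  }
  tibble(chrom = chrom, start = starts, end = starts + lens,
         strand = sample(c("+", "-"), n, replace = TRUE))
}

make_exons <- function(genes, w) {
  list_rbind(pmap(genes, function(chrom, start, end, strand, gene_id, ...) {
    len <- end - start
    e1_end <- snap_bin(start + 0.4 * len, w)
    e2_start <- snap_bin(start + 0.6 * len, w)
    tibble(chrom = chrom,
           start = c(start, e2_start), end = c(e1_end, end),
           strand = strand, gene_id = gene_id)
  }))
}

place_intragenic_states <- function(genes, n, state_width, w) {
  if (n == 0) return(tibble())
  # The antisense eRNA TSS sits at the state center; keep it > 3 kbp
  # downstream of the host TSS (so it classifies as asRNA and never reaches
  # the host promoter) and > 2 kbp from the gene 3' end.
  margin5 <- 3000 + state_width
  margin3 <- 2000 + state_width
  ok <- genes$end - genes$start >= margin5 + margin3 + state_width
  hosts <- genes[ok, , drop = FALSE]
  if (nrow(hosts) < n) {
    abort(sprintf("cannot place %d intragenic states: only %d genes are long enough",
                  n, nrow(hosts)))
  }
  hosts <- hosts[sample.int(nrow(hosts), n), , drop = FALSE]
  start5 <- ifelse(hosts$strand == "+", hosts$start + margin5, hosts$start + margin3)
  end3 <- ifelse(hosts$strand == "+", hosts$end - margin3, hosts$end - margin5)
  s <- snap_bin(runif(n, start5, end3 - state_width), w)
  tibble(chrom = hosts$chrom, start = s, end = s + as.integer(state_width),
         kind = "intragenic", host_gene = hosts$gene_id,
         host_strand = hosts$strand)
}

place_intergenic_states <- function(layout, genes, n, state_width, w,
                                    margin, spacing) {
  if (n == 0) return(tibble())
  cand <- list_rbind(map(layout$chromosomes$chrom, function(ch) {
    g <- arrange(filter(genes, .data$chrom == ch), .data$start)
    bounds <- c(0, as.vector(rbind(g$start, g$end)), layout$chromosomes$length[
      match(ch, layout$chromosomes$chrom)])
    gaps <- matrix(bounds, ncol = 2, byrow = TRUE)  # rows: [gap_start, gap_end]
    list_rbind(map(seq_len(nrow(gaps)), function(i) {
      lo <- gaps[i, 1] + margin
      hi <- gaps[i, 2] - margin - state_width
      if (hi <= lo) return(tibble())
      centers <- seq(snap_bin(lo, w), hi, by = spacing)
      tibble(chrom = ch, start = as.integer(centers))
    }))
  }))
  if (nrow(cand) < n) {
    abort(sprintf(
      "cannot place %d intergenic states with margin %d and spacing %d: only %d candidate slots",
      n, margin, spacing, nrow(cand)))
  }
  cand <- cand[sort(sample.int(nrow(cand), n)), , drop = FALSE]
  tibble(chrom = cand$chrom, start = cand$start,
         end = cand$start + as.integer(state_width),
         kind = "intergenic", host_gene = NA_character_,
         host_strand = NA_character_)
}

# Planted eRNA geometry: for intergenic states a divergent pair around the
# state center; for intragenic states one antisense (relative to the host
# gene) eRNA whose TSS is the state center.
plant_ernas <- function(states, genes, w, erna_gap, erna_length_range) {
  pick_len <- function(n) snap_bin(runif(n, erna_length_range[1], erna_length_range[2]), w)
  out <- list()
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    centre <- snap_bin((st$start + st$end) / 2, w)
    eid <- sub("state", "enh", st$state_id)
    if (st$kind == "intergenic") {
      half <- snap_bin(erna_gap / 2, w)
      tss_minus <- centre - half
      tss_plus <- centre + half
      len <- pick_len(2)
      out[[length(out) + 1]] <- tibble(
        erna_id = paste0(eid, c("_m", "_p")),
        chrom = st$chrom,
        start = c(tss_minus - len[1], tss_plus),
        end = c(tss_minus, tss_plus + len[2]),
        strand = c("-", "+"),
        kind = "bidirectional", state_id = st$state_id, enhancer_id = eid,
        host_gene = NA_character_
      )
    } else {
      # antisense to the host gene; TSS at the state center
      strand <- if (st$host_strand == "+") "-" else "+"
      len <- pick_len(1)
      out[[length(out) + 1]] <- tibble(
        erna_id = paste0(eid, "_a"),
        chrom = st$chrom,
        start = if (strand == "-") centre - len else centre,
        end = if (strand == "-") centre else centre + len,
        strand = strand,
        kind = "antisense", state_id = st$state_id, enhancer_id = eid,
        host_gene = st$host_gene
      )
    }
  }
  list_rbind(out)
}

# Apply the enhancer-region construction rule to the planted eRNAs, giving
# the ground-truth enhancer set the pipeline should recover.
planted_enhancer_regions <- function(ernas) {
  list_rbind(map(split(ernas, ernas$enhancer_id), function(e) {
    if (e$kind[1] == "bidirectional") {
      tsss <- tss(e)
      tibble(enhancer_id = e$enhancer_id[1], chrom = e$chrom[1],
             start = min(tsss) - 500L, end = max(tsss) + 500L,
             kind = "intergenic", host_gene = NA_character_)
    } else {
      t0 <- tss(e)
      if (e$strand == "-") {
        tibble(enhancer_id = e$enhancer_id[1], chrom = e$chrom[1],
               start = t0 - 500L, end = t0 + 750L,
               kind = "intragenic", host_gene = e$host_gene[1])
      } else {
        tibble(enhancer_id = e$enhancer_id[1], chrom = e$chrom[1],
               start = t0 - 750L, end = t0 + 500L,
               kind = "intragenic", host_gene = e$host_gene[1])
      }
    }
  })) |> arrange(.data$chrom, .data$start)
}

#' Write the synthetic annotation to standard files
#'
#' Emits `genes.gtf` (GTF, 1-based), `enhancer_states.bed` (BED6, 0-based)
#' and, per sample in `coverage`, strand-split bedGraph files
#' (`<sample>.plus.bedgraph`, `<sample>.minus.bedgraph`).
#'
#' @param genome A [generate_genome()] result.
#' @param dir Output directory (created if needed).
#' @param coverage Optional named list of [binned_coverage()] objects.
#' @return `dir`, invisibly.
#' @export
write_synthetic_genome <- function(genome, dir, coverage = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- genome$genes
  e <- genome$exons
  gr <- as_granges0(bind_rows(
    mutate(g, feature = "gene"),
    mutate(select(e, all_of(c("chrom", "start", "end", "strand", "gene_id"))),
           biotype = "protein_coding", feature = "exon")
  ))
  gr$type <- c(rep("gene", nrow(g)), rep("exon", nrow(e)))
  gr$gene_id <- c(g$gene_id, e$gene_id)
  gr$gene_biotype <- "protein_coding"
  rtracklayer::export(gr, file.path(dir, "genes.gtf"), format = "gtf")
  write_track(mutate(genome$states, name = .data$state_id, strand = "."),
              file.path(dir, "enhancer_states.bed"), "bed")
  for (nm in names(coverage)) {
    write_track(coverage[[nm]], file.path(dir, paste0(nm, ".plus.bedgraph")),
                "bedgraph", strand = "+")
    write_track(coverage[[nm]], file.path(dir, paste0(nm, ".minus.bedgraph")),
                "bedgraph", strand = "-")
  }
  invisible(dir)
}
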