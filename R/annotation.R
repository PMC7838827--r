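# TU classification relative to protein-coding genes, eRNA calling against
# enhancer-state intervals, enhancer-region construction, and the
# cross-cell-line union annotation.

#' Classification rule constants
#'
#' All distance/fraction constants of the TU classification and eRNA calling
#' rules, overridable in one place.
#'
#' @param promoter_radius Promoter exclusion radius around coding TSSs, bp.
#' @param asrna_downstream TSS distance beyond which an opposite-strand TU is
#'   antisense rather than convergent, bp.
#' @param mrna_overlap Minimal fraction of a coding gene a TU must cover to
#'   be an mRNA.
#' @param state_window Window around an eRNA TSS that must hit an enhancer
#'   state, bp.
#' @param bidirectional_gap Maximal gap between divergent eRNA TSSs, bp.
#' @param antisense_merge_gap Maximal gap for absorbing downstream TUs into
#'   an mRNA/uaRNA readthrough run, bp.
#' @param antisense_fold Minimal eRNA/readthrough FPK fold change.
#' @param upstream_end_window Length of the upstream TU's 3'-end window used
#'   in the fold comparison, bp.
#' @return A list of class `classification_rules`.
#' @export
classification_rules <- function(promoter_radius = 1000,
                                 asrna_downstream = 1000,
                                 mrna_overlap = 0.25,
                                 state_window = 500,
                                 bidirectional_gap = 750,
                                 antisense_merge_gap = 5000,
                                 antisense_fold = 2,
                                 upstream_end_window = 1000) {
  out <- as.list(environment())
  if (any(unlist(out) <= 0)) abort("all classification rule constants must be > 0")
  structure(out, class = "classification_rules")
}

#' Classify transcription units relative to protein-coding genes
#'
#' A TU is an mRNA iff it covers at least 25% of a protein-coding gene on
#' the same strand and overlaps one of its exons. Remaining (non-coding)
#' TUs are classified against the nearest opposite-strand coding gene by
#' TSS position: uaRNA (< 1 kbp upstream of the sense TSS), conRNA (< 1 kbp
#' downstream), asRNA (> 1 kbp downstream, overlapping the gene); everything
#' else is intergenic.
#'
#' @param tus TU tibble (`chrom`, `start`, `end`, `strand`).
#' @param genes Protein-coding gene tibble with `gene_id` (and optionally
#'   `biotype`; non-coding biotypes are ignored).
#' @param exons Exon tibble with `gene_id`.
#' @param rules A [classification_rules()] list.
#' @return `tus` with `class`, `tss`, and `host_gene` columns.
#' @export
classify_tus <- function(tus, genes, exons, rules = classification_rules()) {
  if ("biotype" %in% names(genes)) genes <- filter(genes, .data$biotype == "protein_coding")
  tus$tss <- tss(tus)
  tus$class <- "intergenic"
  tus$host_gene <- NA_character_
  if (nrow(tus) == 0 || nrow(genes) == 0) return(tus)

  tu_gr <- as_granges0(tus)
  gene_gr <- as_granges0(genes)
  exon_gr <- as_granges0(exons)
  gtss <- tss(genes)

  # mRNA: same-strand gene covered >= 25% + exon overlap with that gene
  hits <- GenomicRanges::findOverlaps(tu_gr, gene_gr)
  ov <- GenomicRanges::pintersect(tu_gr[S4Vectors::queryHits(hits)],
                                  gene_gr[S4Vectors::subjectHits(hits)])
  frac <- GenomicRanges::width(ov) /
    GenomicRanges::width(gene_gr[S4Vectors::subjectHits(hits)])
  same <- as.character(GenomicRanges::strand(tu_gr[S4Vectors::queryHits(hits)])) ==
    as.character(GenomicRanges::strand(gene_gr[S4Vectors::subjectHits(hits)]))
  cand <- which(same & frac >= rules$mrna_overlap)
  ex_hits <- GenomicRanges::findOverlaps(tu_gr, exon_gr)
  ex_pairs <- paste(S4Vectors::queryHits(ex_hits),
                    exons$gene_id[S4Vectors::subjectHits(ex_hits)])
  for (k in cand) {
    qi <- S4Vectors::queryHits(hits)[k]
    gid <- genes$gene_id[S4Vectors::subjectHits(hits)[k]]
    if (paste(qi, gid) %in% ex_pairs) {
      tus$class[qi] <- "mRNA"
      tus$host_gene[qi] <- gid
    }
  }

  # non-coding TUs vs opposite-strand genes
  nc <- which(tus$class != "mRNA")
  ov_sets <- map(seq_along(tu_gr), function(i) integer(0))
  opp_hits <- GenomicRanges::findOverlaps(tu_gr, gene_gr, ignore.strand = TRUE)
  for (k in seq_along(opp_hits)) {
    qi <- S4Vectors::queryHits(opp_hits)[k]
    ov_sets[[qi]] <- c(ov_sets[[qi]], S4Vectors::subjectHits(opp_hits)[k])
  }
  for (i in nc) {
    opp <- which(genes$strand != tus$strand[i] & genes$chrom == tus$chrom[i])
    if (length(opp) == 0) next
    # signed TSS distance in the gene's reading direction
    d <- ifelse(genes$strand[opp] == "+", tus$tss[i] - gtss[opp],
                gtss[opp] - tus$tss[i])
    overlaps <- opp %in% ov_sets[[i]]
    keep <- overlaps | abs(d) < rules$promoter_radius
    if (!any(keep)) next
    j <- which(keep)[which.min(abs(d[keep]))]
    dj <- d[j]
    tus$host_gene[i] <- genes$gene_id[opp[j]]
    if (dj <= 0 && abs(dj) < rules$promoter_radius) {
      # TSS at or upstream of the sense TSS: divergent (upstream antisense)
      tus$class[i] <- "uaRNA"
    } else if (dj > 0 && dj < rules$asrna_downstream) {
      tus$class[i] <- "conRNA"
    } else if (dj >= rules$asrna_downstream && overlaps[j]) {
      tus$class[i] <- "asRNA"
    } else {
      tus$host_gene[i] <- NA_character_
    }
  }
  tus
}

#' Call eRNAs from classified non-coding TUs
#'
#' Keeps asRNA and intergenic TUs whose TSS +- 500 bp intersects an
#' enhancer-state interval, drops TUs overlapping small-RNA annotations or
#' an explicit lncRNA exclusion list, and truncates long antisense eRNAs
#' that reach their host gene's promoter (TSS +- 1 kbp) to end 1 kbp
#' downstream of the coding TSS.
#'
#' @param nc_tus Classified TU tibble (from [classify_tus()]).
#' @param enhancer_states Enhancer-state interval tibble.
#' @param genes Protein-coding genes (for the truncation rule).
#' @param exclusions Optional interval tibble (small RNAs, functional
#'   lncRNAs); overlapping TUs are dropped.
#' @param rules A [classification_rules()] list.
#' @return eRNA tibble with `erna_id`, `kind` (`"antisense"`/`"intergenic"`).
#' @export
call_ernas <- function(nc_tus, enhancer_states, genes, exclusions = NULL,
                       rules = classification_rules()) {
  er <- filter(nc_tus, .data$class %in% c("asRNA", "intergenic"))
  if (nrow(er) > 0 && nrow(genes) > 0) {
    # promoter exclusion: no eRNA TSS within 1 kbp of a coding TSS
    gtss <- tss(if ("biotype" %in% names(genes)) {
      filter(genes, .data$biotype == "protein_coding")
    } else genes)
    near <- map_lgl_(seq_len(nrow(er)), function(i) {
      any(genes$chrom == er$chrom[i] &
            abs(gtss - er$tss[i]) < rules$promoter_radius)
    })
    er <- er[!near, , drop = FALSE]
  }
  if (nrow(er) == 0) {
    return(mutate(er, erna_id = character(0), kind = character(0)))
  }
  tss_win <- tibble(chrom = er$chrom,
                    start = pmax(0, er$tss - rules$state_window),
                    end = er$tss + rules$state_window)
  hit <- GenomicRanges::countOverlaps(as_granges0(tss_win),
                                      as_granges0(select(enhancer_states,
                                                         all_of(c("chrom", "start", "end")))),
                                      ignore.strand = TRUE) > 0
  er <- er[hit, , drop = FALSE]
  if (!is.null(exclusions) && nrow(exclusions) > 0 && nrow(er) > 0) {
    drop <- GenomicRanges::countOverlaps(as_granges0(er), as_granges0(exclusions),
                                         ignore.strand = TRUE) > 0
    er <- er[!drop, , drop = FALSE]
  }
  # truncate antisense eRNAs reaching the host promoter
  if (nrow(er) > 0) {
    gtss <- setNames(tss(genes), genes$gene_id)
    for (i in which(er$class == "asRNA")) {
      g <- er$host_gene[i]
      if (is.na(g)) next
      p_lo <- gtss[g] - rules$promoter_radius
      p_hi <- gtss[g] + rules$promoter_radius
      if (er$start[i] < p_hi && er$end[i] > p_lo) {   # overlaps promoter window
        host_strand <- genes$strand[match(g, genes$gene_id)]
        if (host_strand == "+") {
          er$start[i] <- max(er$start[i], gtss[g] + rules$promoter_radius)
        } else {
          er$end[i] <- min(er$end[i], gtss[g] - rules$promoter_radius)
        }
      }
    }
    er <- filter(er, .data$end > .data$start)
  }
  er$erna_id <- if (nrow(er) > 0) sprintf("eRNA%05d", seq_len(nrow(er))) else character(0)
  er$kind <- if_else(er$class == "asRNA", "antisense", "intergenic")
  er
}

#' Drop antisense eRNAs that look like readthrough transcription
#'
#' Highly transcribed TUs shed spurious downstream TUs. Walking each strand
#' in the direction of transcription, non-coding TUs downstream of an
#' mRNA/uaRNA are absorbed into a merged run while successive gaps stay
#' below 5 kbp; antisense eRNAs inside such runs are kept only if their FPK
#' is at least 2-fold the FPK over the last 1 kbp of the upstream
#' mRNA/uaRNA.
#'
#' @param ernas eRNA tibble (from [call_ernas()]).
#' @param tus Full classified TU tibble for the same cell line.
#' @param coverage The cell line's pooled [binned_coverage()].
#' @param size_factor The sample's size factor (scalar).
#' @param rules A [classification_rules()] list.
#' @return Filtered eRNA tibble.
#' @export
filter_antisense <- function(ernas, tus, coverage, size_factor = 1,
                             rules = classification_rules()) {
  if (nrow(ernas) == 0) return(ernas)
  drop_ids <- character(0)
  fpk_of <- function(chrom, start, end, strand) {
    cnt <- count_fragments(tibble(chrom = chrom, start = start, end = end,
                                  strand = strand), coverage, "sense")
    (cnt / size_factor) / ((end - start) / 1000)
  }
  for (str in c("+", "-")) {
    g <- arrange(filter(tus, .data$strand == str), .data$chrom, .data$start)
    if (str == "-") g <- arrange(g, .data$chrom, dplyr::desc(.data$end))
    for (ch in unique(g$chrom)) {
      gc <- filter(g, .data$chrom == ch)
      anchor <- NULL
      prev_3p <- NULL
      for (i in seq_len(nrow(gc))) {
        row <- gc[i, ]
        gap <- if (is.null(prev_3p)) Inf else {
          if (str == "+") row$start - prev_3p else prev_3p - row$end
        }
        in_run <- !is.null(anchor) && gap < rules$antisense_merge_gap && gap >= 0
        if (row$class %in% c("mRNA", "uaRNA")) {
          anchor <- row                       # new run anchored here
        } else if (in_run && row$tu_id %in% ernas$tu_id) {
          a3 <- tes(anchor)
          win <- if (anchor$strand == "+") {
            c(a3 - rules$upstream_end_window, a3)
          } else c(a3, a3 + rules$upstream_end_window)
          up_fpk <- fpk_of(ch, win[1], win[2], anchor$strand)
          er_fpk <- fpk_of(ch, row$start, row$end, row$strand)
          if (er_fpk < rules$antisense_fold * up_fpk) {
            drop_ids <- c(drop_ids, row$tu_id)
          }
        } else if (!in_run) {
          anchor <- NULL                      # chain broken by a big gap
        }
        prev_3p <- if (str == "+") max(row$end, prev_3p %||% -Inf) else
          min(row$start, prev_3p %||% Inf)
      }
    }
  }
  filter(ernas, !(.data$tu_id %in% drop_ids) | .data$kind != "antisense")
}

#' Pair divergent intergenic eRNAs
#'
#' Each intergenic eRNA is paired with the nearest opposite-strand
#' non-coding TU whose TSS forms a divergent configuration with a gap of at
#' most 750 bp (overlap allowed; the partner need not pass the expression
#' threshold). Unpaired intergenic eRNAs are discarded.
#'
#' @param intergenic_ernas Intergenic eRNA tibble.
#' @param nc_tus All non-coding TUs (partner candidates).
#' @param rules A [classification_rules()] list.
#' @return Tibble of pairs: plus/minus TSSs, `gap`, constituent ids.
#' @export
pair_bidirectional <- function(intergenic_ernas, nc_tus,
                               rules = classification_rules()) {
  er <- filter(intergenic_ernas, .data$kind == "intergenic")
  out <- list()
  cand_all <- filter(nc_tus, .data$class != "mRNA")
  cand_all$tss <- tss(cand_all)
  for (i in seq_len(nrow(er))) {
    e <- er[i, ]
    cand <- filter(cand_all, .data$chrom == e$chrom, .data$strand != e$strand)
    if (nrow(cand) == 0) next
    if (e$strand == "+") {
      p_start <- e$start; p_end <- e$end; p_tss <- e$tss
      m_start <- cand$start; m_end <- cand$end; m_tss <- cand$tss
    } else {
      p_start <- cand$start; p_end <- cand$end; p_tss <- cand$tss
      m_start <- e$start; m_end <- e$end; m_tss <- e$tss
    }
    gap <- p_tss - m_tss
    divergent <- (p_start >= m_start) & (p_end >= m_end) & (gap <= rules$bidirectional_gap)
    if (!any(divergent)) next
    j <- which(divergent)
    j <- j[order(abs(gap[j]), cand$start[j])][1]   # nearest TSS, leftmost tie
    out[[length(out) + 1]] <- tibble(
      chrom = e$chrom,
      erna_id = e$erna_id,
      partner_id = cand$tu_id[j],
      tss_plus = if (e$strand == "+") e$tss else cand$tss[j],
      tss_minus = if (e$strand == "+") cand$tss[j] else e$tss,
      gap = gap[if (e$strand == "+") j else j]
    )
  }
  if (length(out) == 0) {
    return(tibble(chrom = character(), erna_id = character(),
                  partner_id = character(), tss_plus = numeric(),
                  tss_minus = numeric(), gap = numeric()))
  }
  # a divergent pair of two intergenic eRNAs is found from both sides;
  # keep one record per distinct TSS pair
  distinct(list_rbind(out), .data$chrom, .data$tss_plus, .data$tss_minus,
           .keep_all = TRUE)
}

#' Construct putative enhancer regions
#'
#' Intergenic enhancers span the interval between the two divergent eRNA
#' TSSs extended by 500 bp on both sides; intragenic enhancers cover 750 bp
#' upstream to 500 bp downstream of the antisense eRNA TSS (strand-aware),
#' so every intragenic region is exactly 1,250 bp long.
#'
#' @param pairs Divergent pairs from [pair_bidirectional()].
#' @param antisense_ernas Antisense eRNA tibble.
#' @param layout Optional [genome_layout()] for boundary clipping.
#' @return Enhancer-region tibble: `enhancer_id`, `chrom`, `start`, `end`,
#'   `kind`, `erna_strand` (intragenic), `constituents`.
#' @export
define_enhancers <- function(pairs, antisense_ernas = NULL, layout = NULL) {
  inter <- if (nrow(pairs) > 0) {
    tibble(chrom = pairs$chrom,
           start = pmin(pairs$tss_plus, pairs$tss_minus) - 500,
           end = pmax(pairs$tss_plus, pairs$tss_minus) + 500,
           kind = "intergenic",
           erna_strand = NA_character_,
           constituents = paste(pairs$erna_id, pairs$partner_id, sep = ","))
  } else tibble()
  intra <- if (!is.null(antisense_ernas) && nrow(antisense_ernas) > 0) {
    a <- filter(antisense_ernas, .data$kind == "antisense")
    t0 <- tss(a)
    tibble(chrom = a$chrom,
           start = ifelse(a$strand == "-", t0 - 500, t0 - 750),
           end = ifelse(a$strand == "-", t0 + 750, t0 + 500),
           kind = "intragenic",
           erna_strand = a$strand,
           constituents = a$erna_id)
  } else tibble()
  out <- bind_rows(inter, intra)
  if (nrow(out) == 0) {
    return(tibble(enhancer_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), kind = character(),
                  erna_strand = character(), constituents = character()))
  }
  if (!is.null(layout)) {
    lens <- setNames(layout$chromosomes$length, layout$chromosomes$chrom)
    clipped <- out$start < 0 | out$end > lens[out$chrom]
    if (any(clipped)) {
      warn(sprintf("%d enhancer region(s) clipped at chromosome bounds", sum(clipped)))
      out$start <- pmax(out$start, 0)
      out$end <- pmin(out$end, lens[out$chrom])
    }
  }
  out <- arrange(out, .data$chrom, .data$start)
  out$enhancer_id <- sprintf("ENH%05d", seq_len(nrow(out)))
  select(out, all_of(c("enhancer_id", "chrom", "start", "end", "kind",
                       "erna_strand", "constituents")))
}

#' Merge per-cell-line annotations into a union set
#'
#' Overlapping intervals from different cell lines are collapsed into their
#' union (transitive interval merge); the source cell lines of every merged
#' record are retained.
#'
#' @param per_line Named list of interval tibbles (one per cell line).
#' @return Merged tibble with `sources` (comma-joined cell lines),
#'   `n_sources`, and `kind` (`"mixed"` when constituents disagree).
#' @export
merge_across_cell_lines <- function(per_line) {
  if (length(per_line) == 0) abort("need at least one cell line")
  all_df <- list_rbind(imap(per_line, function(df, nm) mutate(df, .line = nm)))
  if (nrow(all_df) == 0) {
    return(tibble(chrom = character(), start = numeric(), end = numeric(),
                  kind = character(), sources = character(), n_sources = integer()))
  }
  gr <- as_granges0(mutate(all_df, strand = "."))
  red <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
  hits <- GenomicRanges::findOverlaps(red, gr)
  out <- granges_to_tibble(red)
  out$strand <- NULL
  grp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  out$sources <- map_chr(seq_len(nrow(out)), function(i) {
    paste(sort(unique(all_df$.line[grp[[as.character(i)]]])), collapse = ",")
  })
  out$n_sources <- map_int(strsplit(out$sources, ","), length)
  if ("kind" %in% names(all_df)) {
    out$kind <- map_chr(seq_len(nrow(out)), function(i) {
      k <- unique(all_df$kind[grp[[as.character(i)]]])
      if (length(k) == 1) k else "mixed"
    })
  }
  if ("erna_strand" %in% names(all_df)) {
    out$erna_strand <- map_chr(seq_len(nrow(out)), function(i) {
      s <- unique(all_df$erna_strand[grp[[as.character(i)]]])
      s <- s[!is.na(s)]
      if (length(s) == 1) s else NA_character_
    })
  }
  out$merged_id <- sprintf("MENH%05d", seq_len(nrow(out)))
  out
}

#' Quantify enhancer transcription into an activity matrix
#'
#' Intragenic enhancers count antisense-strand fragments only (effective
#' length = width - 750 bp); intergenic (and mixed merged) enhancers sum
#' both strands (effective length = width).
#'
#' @param regions Enhancer-region tibble with `kind` and `erna_strand`.
#' @param coverage_list Named list of per-sample [binned_coverage()].
#' @param size_factors Named size factors per sample.
#' @param sample_lines Named map sample -> cell line (for replicate
#'   averaging).
#' @return An [fpk()] `activity_matrix`.
#' @export
quantify_enhancers <- function(regions, coverage_list, size_factors,
                               sample_lines = NULL) {
  intra <- regions$kind == "intragenic" & !is.na(regions$erna_strand)
  eff_len <- (regions$end - regions$start) - ifelse(intra, 750, 0)
  qry <- mutate(regions,
                strand = if_else(intra, .data$erna_strand, "+"))
  counts <- sapply(coverage_list, function(cv) {
    cnt <- numeric(nrow(qry))
    if (any(intra)) cnt[intra] <- count_fragments(qry[intra, ], cv, "sense")
    if (any(!intra)) cnt[!intra] <- count_fragments(qry[!intra, ], cv, "both")
    cnt
  })
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nrow(qry))
  colnames(counts) <- names(coverage_list)
  rn <- if ("merged_id" %in% names(regions)) regions$merged_id else regions$enhancer_id
  rownames(counts) <- rn
  fpk(counts, size_factors[colnames(counts)], eff_len, sample_lines)
}
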