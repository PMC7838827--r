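# Enhancer-promoter pairing: nearest (N), correlated-neighboring (CN) and
# correlated-window (CW). Distances run from enhancer midpoints to gene
# TSSs; correlations are Pearson r of log2(FPK + 1) across cell lines.

pair_r <- function(enh_act, prom_act, enhancer_id, gene_id) {
  a <- log2(enh_act[enhancer_id, ] + 1)
  b <- log2(prom_act[gene_id, ] + 1)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  cor(a, b)
}

# Pearson r of log2(FPK + 1) between one enhancer and many promoters.
pair_r_many <- function(enh_log, prom_log, enhancer_id, gene_ids) {
  a <- enh_log[enhancer_id, ]
  if (stats::sd(a) == 0) return(rep(NA_real_, length(gene_ids)))
  b <- t(prom_log[gene_ids, , drop = FALSE])
  r <- suppressWarnings(as.vector(cor(a, b)))
  r[apply(b, 2, stats::sd) == 0] <- NA_real_
  r
}

prepare_promoters <- function(promoters_active) {
  p <- promoters_active
  p$tss <- tss(p)
  arrange(p, .data$chrom, .data$tss)
}

#' Pair enhancers to their nearest active promoter (N)
#'
#' Each enhancer is linked to the single nearest active gene TSS by
#' midpoint distance; pairs spanning 500 kbp or more are dropped. No
#' correlation filter. Equidistant promoters resolve to the leftmost TSS.
#'
#' @param enhancers Enhancer-region tibble.
#' @param promoters_active Active-promoter tibble (genes with FPK >= 30),
#'   with `gene_id`.
#' @param max_distance Strict distance bound in bp (default 500 kbp).
#' @return EPPair tibble: `enhancer_id`, `gene_id`, `method = "N"`,
#'   `distance`, `r = NA`.
#' @export
pair_nearest <- function(enhancers, promoters_active, max_distance = 5e5) {
  p <- prepare_promoters(promoters_active)
  id_col <- if ("merged_id" %in% names(enhancers)) enhancers$merged_id else enhancers$enhancer_id
  mid <- (enhancers$start + enhancers$end) / 2
  out <- list()
  for (i in seq_len(nrow(enhancers))) {
    cand <- p[p$chrom == enhancers$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    d <- abs(cand$tss - mid[i])
    j <- which(d == min(d))
    j <- j[which.min(cand$tss[j])]               # leftmost TSS on ties
    if (d[j] >= max_distance) next
    out[[length(out) + 1]] <- tibble(enhancer_id = id_col[i],
                                     gene_id = cand$gene_id[j],
                                     method = "N", distance = d[j], r = NA_real_)
  }
  bind_rows(tibble(enhancer_id = character(), gene_id = character(),
                   method = character(), distance = numeric(), r = numeric()),
            list_rbind(out))
}

#' Pair enhancers to correlated neighboring promoters (CN)
#'
#' Candidates are the nearest active promoter on each side of the enhancer
#' midpoint (at most two); candidates are kept when the across-cell-line
#' Pearson correlation of log2(FPK + 1) strictly exceeds `min_r` and the
#' distance stays below `max_distance`.
#'
#' @inheritParams pair_nearest
#' @param enhancer_activity,promoter_activity Feature-by-cell-line FPK
#'   matrices (rownames = ids).
#' @param min_r Strict correlation threshold (default 0.6).
#' @return EPPair tibble with `method = "CN"` and `r`.
#' @export
pair_correlated_neighboring <- function(enhancers, promoters_active,
                                        enhancer_activity, promoter_activity,
                                        min_r = 0.6, max_distance = 5e5) {
  p <- prepare_promoters(promoters_active)
  id_col <- if ("merged_id" %in% names(enhancers)) enhancers$merged_id else enhancers$enhancer_id
  mid <- (enhancers$start + enhancers$end) / 2
  out <- list()
  for (i in seq_len(nrow(enhancers))) {
    cand <- p[p$chrom == enhancers$chrom[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    left <- cand[cand$tss <= mid[i], , drop = FALSE]
    right <- cand[cand$tss > mid[i], , drop = FALSE]
    picks <- bind_rows(
      if (nrow(left) > 0) tail(left, 1) else NULL,
      if (nrow(right) > 0) head(right, 1) else NULL
    )
    for (k in seq_len(nrow(picks))) {
      d <- abs(picks$tss[k] - mid[i])
      if (d >= max_distance) next
      r <- pair_r(enhancer_activity, promoter_activity, id_col[i], picks$gene_id[k])
      if (!is.na(r) && r > min_r) {
        out[[length(out) + 1]] <- tibble(enhancer_id = id_col[i],
                                         gene_id = picks$gene_id[k],
                                         method = "CN", distance = d, r = r)
      }
    }
  }
  bind_rows(tibble(enhancer_id = character(), gene_id = character(),
                   method = character(), distance = numeric(), r = numeric()),
            list_rbind(out))
}

#' Pair enhancers to all correlated promoters in a window (CW)
#'
#' All active promoters within `window` of the enhancer midpoint are
#' candidates; those with r > `min_r` are kept. Every pair carries a
#' `skip` flag: whether at least one active promoter lies strictly between
#' the enhancer and its target.
#'
#' @inheritParams pair_correlated_neighboring
#' @param window Half-window around the enhancer midpoint, bp.
#' @param keep_all Also return rejected candidates (full candidate table
#'   with `kept` flag) as attribute `"candidates"`.
#' @return EPPair tibble with `method = "CW"`, `r`, `skip`.
#' @export
pair_correlated_window <- function(enhancers, promoters_active,
                                   enhancer_activity, promoter_activity,
                                   min_r = 0.6, window = 5e5,
                                   keep_all = FALSE) {
  p <- prepare_promoters(promoters_active)
  id_col <- if ("merged_id" %in% names(enhancers)) enhancers$merged_id else enhancers$enhancer_id
  mid <- (enhancers$start + enhancers$end) / 2
  enh_log <- log2(enhancer_activity + 1)
  prom_log <- log2(promoter_activity + 1)
  cand_tab <- list()
  for (i in seq_len(nrow(enhancers))) {
    cand <- p[p$chrom == enhancers$chrom[i], , drop = FALSE]
    d <- abs(cand$tss - mid[i])
    cand <- cand[d < window, , drop = FALSE]
    d <- d[d < window]
    if (nrow(cand) == 0) next
    r <- pair_r_many(enh_log, prom_log, id_col[i], cand$gene_id)
    skip <- map_lgl_(seq_len(nrow(cand)), function(k) {
      any(cand$tss > min(mid[i], cand$tss[k]) &
            cand$tss < max(mid[i], cand$tss[k]) &
            seq_len(nrow(cand)) != k)
    })
    cand_tab[[length(cand_tab) + 1]] <- tibble(
      enhancer_id = id_col[i], gene_id = cand$gene_id, method = "CW",
      distance = d, r = r, skip = skip, kept = !is.na(r) & r > min_r)
  }
  empty <- tibble(enhancer_id = character(), gene_id = character(),
                  method = character(), distance = numeric(), r = numeric(),
                  skip = logical(), kept = logical())
  all_cand <- bind_rows(empty, list_rbind(cand_tab))
  res <- select(filter(all_cand, .data$kept), -"kept")
  if (keep_all) attr(res, "candidates") <- all_cand
  res
}

#' Summaries of an E-P pair set
#'
#' Per-promoter enhancer counts per cell line and over the union of paired
#' enhancers, plus the fractions of enhancers pairing only to neighboring
#' promoters, only past a skipped promoter, or both.
#'
#' @param pairs EPPair tibble; a `cell_line` column (one row per pair and
#'   line) enables per-line summaries, a `skip` column the skip fractions.
#' @return A list with `per_promoter` (tibble), `mean_enhancers_per_promoter`
#'   (per line and union), and `skip_fractions`.
#' @export
pairing_summaries <- function(pairs) {
  if (nrow(pairs) == 0) {
    return(list(per_promoter = tibble(gene_id = character(), n_enhancers = integer()),
                mean_enhancers_per_promoter = c(per_line = NA_real_, union = NA_real_),
                skip_fractions = c(neighbor_only = NA_real_, skipped_only = NA_real_,
                                   both = NA_real_)))
  }
  union_tab <- summarise(group_by(distinct(pairs, .data$gene_id, .data$enhancer_id),
                                  .data$gene_id),
                         n_enhancers = n(), .groups = "drop")
  per_line_mean <- if ("cell_line" %in% names(pairs)) {
    line_counts <- summarise(group_by(pairs, .data$cell_line, .data$gene_id),
                             n = dplyr::n_distinct(.data$enhancer_id), .groups = "drop")
    mean(line_counts$n)
  } else NA_real_
  skip_fr <- if ("skip" %in% names(pairs)) {
    by_enh <- summarise(group_by(pairs, .data$enhancer_id),
                        any_skip = any(.data$skip), all_skip = all(.data$skip),
                        .groups = "drop")
    c(neighbor_only = mean(!by_enh$any_skip),
      skipped_only = mean(by_enh$all_skip),
      both = mean(by_enh$any_skip & !by_enh$all_skip))
  } else c(neighbor_only = NA_real_, skipped_only = NA_real_, both = NA_real_)
  list(per_promoter = union_tab,
       mean_enhancers_per_promoter = c(per_line = per_line_mean,
                                       union = mean(union_tab$n_enhancers)),
       skip_fractions = skip_fr)
}
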