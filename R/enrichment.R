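# Super-enhancer calling, interaction support of E-P pairs, matched-null
# resampling ensembles, and gene-class enrichment tests.

new_null_ensemble <- function(observed, nulls, seed = NA_integer_,
                              statistic = "statistic") {
  n <- length(nulls)
  structure(list(
    observed = observed, nulls = nulls, n_resamples = n,
    p = (1 + sum(nulls >= observed)) / (1 + n),
    statistic = statistic, seed = seed
  ), class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %s: observed %.4g vs %d matched nulls (median %.4g), empirical p = %.4g\n",
              x$statistic, x$observed, x$n_resamples, median(x$nulls), x$p))
  invisible(x)
}

#' @export
tidy.null_ensemble <- function(x, ...) {
  tibble(resample = seq_len(x$n_resamples), statistic = x$nulls)
}

#' @export
glance.null_ensemble <- function(x, ...) {
  tibble(observed = x$observed, null_median = median(x$nulls),
         null_mean = mean(x$nulls), n_resamples = x$n_resamples,
         p_empirical = x$p)
}

#' @export
autoplot.null_ensemble <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed, color = "red", linewidth = 1) +
    ggplot2::labs(x = object$statistic, y = "matched null sets",
                  title = sprintf("observed vs %d matched nulls (p = %.3g)",
                                  object$n_resamples, object$p)) +
    ggplot2::theme_minimal()
}

#' Serialize a null ensemble to TSV + JSON summary
#'
#' @param x A `null_ensemble`.
#' @param path_prefix Files `<prefix>.tsv` (per-resample statistics) and
#'   `<prefix>.json` (observed, p, n_sets, seed) are written.
#' @return `path_prefix`, invisibly.
#' @export
write_null_ensemble <- function(x, path_prefix) {
  utils::write.table(tidy(x), paste0(path_prefix, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(observed = x$observed, p = x$p,
                            n_sets = x$n_resamples, seed = x$seed),
                       paste0(path_prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path_prefix)
}

#' Call super-enhancers by stitching and ranked-signal inflection
#'
#' Same-chromosome peaks with gaps under `stitch_gap` are stitched into
#' regions; regions are ranked by total signal (ascending), rank and signal
#' are min-max rescaled to `[0, 1]`, and the cutoff sits where the discrete
#' slope (central differences) of signal vs rank first exceeds 1 — the
#' tangent-slope-one rule on the hockey-stick curve. Regions above the
#' cutoff are super-enhancers.
#'
#' @param peaks Tibble with `chrom`, `start`, `end`, `signal` (and
#'   optionally `peak_id`).
#' @param stitch_gap Strict stitching distance, bp (default 12,500).
#' @return Tibble of stitched regions: `chrom`, `start`, `end`,
#'   `constituents`, `total_signal`, `rank`, `is_super`. Class
#'   `super_enhancer_calls`.
#' @export
call_super_enhancers <- function(peaks, stitch_gap = 12500) {
  if (any(peaks$signal < 0)) abort("peak signal must be nonnegative")
  if (!"peak_id" %in% names(peaks)) peaks$peak_id <- sprintf("peak%05d", seq_len(nrow(peaks)))
  st <- list_rbind(map(split(peaks, peaks$chrom), function(g) {
    g <- arrange(g, .data$start)
    grp <- cumsum(c(1, as.integer(g$start[-1] - cummax(g$end)[-nrow(g)] >= stitch_gap)))
    summarise(group_by(g, grp = grp),
              chrom = first(.data$chrom), start = min(.data$start),
              end = max(.data$end),
              constituents = paste(.data$peak_id, collapse = ","),
              constituent_starts = paste(.data$start, collapse = ","),
              constituent_ends = paste(.data$end, collapse = ","),
              total_signal = sum(.data$signal), .groups = "drop") |>
      select(-"grp")
  }))
  st <- arrange(st, .data$total_signal)
  st$rank <- seq_len(nrow(st))
  st$is_super <- FALSE
  if (nrow(st) < 3) {
    warn("fewer than 3 stitched regions; inflection undefined, all typical")
  } else {
    x <- (st$rank - 1) / (nrow(st) - 1)
    y <- st$total_signal
    if (max(y) > min(y)) {
      y <- (y - min(y)) / (max(y) - min(y))
      slope <- slope_central(x, y)
      above <- which(slope > 1)
      if (length(above) > 0) st$is_super[st$rank > min(above)] <- TRUE
    }
  }
  class(st) <- c("super_enhancer_calls", class(st))
  st
}

slope_central <- function(x, y) {
  n <- length(x)
  s <- numeric(n)
  s[1] <- (y[2] - y[1]) / (x[2] - x[1])
  s[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    s[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  s
}

#' @export
autoplot.super_enhancer_calls <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$total_signal,
                                       color = .data$is_super)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey50", `TRUE` = "red")) +
    ggplot2::labs(x = "region rank (by total signal)", y = "total signal",
                  color = "super-enhancer") +
    ggplot2::theme_minimal()
}

#' Interaction (CHi-C-like) support of E-P pairs
#'
#' A pair is supported iff some interaction with score >= `min_score` has
#' its bait fragment covering the promoter TSS and its hit fragment
#' overlapping the enhancer region. Pairs at distance <= `min_distance`
#' are excluded from the denominator (short-range interactions are not
#' reliably measurable).
#'
#' @param pairs EPPair tibble with `enhancer_id`, `gene_id`, `distance`.
#' @param enhancers Enhancer-region tibble keyed by the pair ids.
#' @param promoters Gene/promoter tibble with `gene_id`, coordinates, strand.
#' @param interactions Tibble with `bait_chrom`, `bait_start`, `bait_end`,
#'   `hit_chrom`, `hit_start`, `hit_end`, `score`.
#' @param min_score Minimal interaction score (default 3.0, inclusive).
#' @param min_distance Pairs at or under this distance are excluded, bp.
#' @return A list: `pairs` (eligible pairs with `supported` flag) and
#'   `fraction_supported`.
#' @export
chic_support <- function(pairs, enhancers, promoters, interactions,
                         min_score = 3.0, min_distance = 10000) {
  inter <- filter(interactions, .data$score >= min_score)
  eligible <- filter(pairs, .data$distance > min_distance)
  if (nrow(eligible) == 0) {
    return(list(pairs = mutate(eligible, supported = logical(0)),
                fraction_supported = NA_real_))
  }
  enh_key <- if ("merged_id" %in% names(enhancers)) enhancers$merged_id else enhancers$enhancer_id
  ptss <- setNames(tss(promoters), promoters$gene_id)
  pchrom <- setNames(promoters$chrom, promoters$gene_id)
  supported <- map_lgl_(seq_len(nrow(eligible)), function(k) {
    e <- enhancers[match(eligible$enhancer_id[k], enh_key), ]
    t0 <- ptss[eligible$gene_id[k]]
    any(inter$bait_chrom == pchrom[eligible$gene_id[k]] &
          inter$bait_start <= t0 & inter$bait_end > t0 &
          inter$hit_chrom == e$chrom &
          inter$hit_start < e$end & inter$hit_end > e$start)
  })
  eligible$supported <- supported
  list(pairs = eligible, fraction_supported = mean(supported))
}

#' Fisher's exact enrichment on a 2x2 table
#'
#' Odds ratio by the sample convention `(a d) / (b c)` (infinite when
#' `b c = 0` and `a d > 0`); two-sided exact p-value from the
#' hypergeometric distribution.
#'
#' @param in_group_and_paired,in_group_not_paired,out_group_paired,out_group_not_paired
#'   The four nonnegative cell counts (a, b, c, d).
#' @return Tibble with `odds_ratio` and `p_value`.
#' @export
fisher_enrichment <- function(in_group_and_paired, in_group_not_paired,
                              out_group_paired, out_group_not_paired) {
  cells <- c(in_group_and_paired, in_group_not_paired,
             out_group_paired, out_group_not_paired)
  if (any(cells < 0)) abort("cell counts must be nonnegative")
  if (sum(cells) == 0) abort("the table must contain at least one observation")
  a <- cells[1]; b <- cells[2]; c <- cells[3]; d <- cells[4]
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  p <- fisher.test(matrix(cells, 2, 2, byrow = TRUE))$p.value
  tibble(odds_ratio = or, p_value = p)
}

# ---- matched-null machinery -------------------------------------------

# Joint decile-bin matching: draw, for every observed row, one candidate
# from the same joint bin of the covariates (nearest nonempty bin fallback).
# matched_sampler() precomputes the binning once; the returned closure draws
# one matched index set per call.
matched_sampler <- function(obs_cov, pool_cov) {
  stopifnot(ncol(obs_cov) == ncol(pool_cov))
  nb <- ncol(obs_cov)
  obs_bins <- matrix(0L, nrow(obs_cov), nb)
  pool_bins <- matrix(0L, nrow(pool_cov), nb)
  for (j in seq_len(nb)) {
    ref <- pool_cov[[j]]
    obs_bins[, j] <- decile_bin(obs_cov[[j]], ref)
    pool_bins[, j] <- decile_bin(pool_cov[[j]], ref)
  }
  pool_key <- apply(pool_bins, 1, paste, collapse = "/")
  pool_by_bin <- split(seq_len(nrow(pool_cov)), pool_key)
  keys <- unique(pool_key)
  key_mat <- do.call(rbind, strsplit(keys, "/"))
  storage.mode(key_mat) <- "integer"
  fell_back <- FALSE
  # resolve every observed row to its candidate pool once
  cand_sets <- map(seq_len(nrow(obs_cov)), function(i) {
    cand <- pool_by_bin[[paste(obs_bins[i, ], collapse = "/")]]
    if (is.null(cand)) {
      fell_back <<- TRUE
      dd <- rowSums(abs(sweep(key_mat, 2, obs_bins[i, ])))
      cand <- pool_by_bin[[keys[which.min(dd)]]]
    }
    cand
  })
  if (fell_back) {
    warn("some matching bins were empty; fell back to nearest nonempty bins",
         .frequency = "once", .frequency_id = "enhancertx_bin_fallback")
  }
  function() {
    map_int(cand_sets, function(cand) cand[sample.int(length(cand), 1)])
  }
}

matched_sample_idx <- function(obs_cov, pool_cov) matched_sampler(obs_cov, pool_cov)()

# Fast point-in-interval counter over a (possibly overlapping) region set.
region_counter <- function(regions) {
  red <- GenomicRanges::reduce(as_granges0(
    mutate(regions[c("chrom", "start", "end")], strand = ".")),
    ignore.strand = TRUE)
  df <- granges_to_tibble(red)
  by_chrom <- split(df, df$chrom)
  by_chrom <- map(by_chrom, function(d) d[order(d$start), , drop = FALSE])
  function(chrom, pos) {
    hit <- logical(length(pos))
    for (ch in unique(chrom)) {
      d <- by_chrom[[ch]]
      sel <- chrom == ch
      if (is.null(d)) next
      i <- findInterval(pos[sel], d$start)
      hit[sel] <- i > 0 & pos[sel] < d$end[pmax(i, 1)]
    }
    hit
  }
}

#' Matched-null ensemble for interaction support of E-P pairs
#'
#' Draws `n_sets` random E-P pair sets matched to the observed one:
#' promoters are resampled from the active-promoter pool by joint decile
#' bins of transcription level and overall specificity, and each is paired
#' to a random non-coding region matching the observed enhancer widths and
#' E-P distances (decile bins). Interaction support is recomputed per set
#' and an empirical p-value reported with the plus-one rule.
#'
#' @param pairs Observed EPPair tibble.
#' @param enhancers Enhancer regions for the observed pairs.
#' @param promoters Promoter pool tibble with `gene_id`, coordinates,
#'   `activity` (FPK) and `specificity` columns.
#' @param interactions Interaction table (see [chic_support()]).
#' @param layout A [genome_layout()] for placing random regions.
#' @param genes Gene tibble; random regions avoid gene promoters.
#' @param n_sets Number of matched null sets (default 100).
#' @param seed Mandatory RNG seed.
#' @param min_score,min_distance Passed to [chic_support()].
#' @return A `null_ensemble` of the supported fraction.
#' @export
sample_matched_ep_nulls <- function(pairs, enhancers, promoters, interactions,
                                    layout, genes, n_sets = 100, seed,
                                    min_score = 3.0, min_distance = 10000) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_sets <= 0) abort("n_sets must be positive")
  stopifnot(all(c("activity", "specificity") %in% names(promoters)))
  obs <- chic_support(pairs, enhancers, promoters, interactions,
                      min_score, min_distance)
  enh_key <- if ("merged_id" %in% names(enhancers)) enhancers$merged_id else enhancers$enhancer_id
  ei <- match(pairs$enhancer_id, enh_key)
  widths <- (enhancers$end - enhancers$start)[ei]
  pi_ <- match(pairs$gene_id, promoters$gene_id)
  obs_cov <- tibble(activity = promoters$activity[pi_],
                    specificity = promoters$specificity[pi_])
  pool_cov <- tibble(activity = promoters$activity,
                     specificity = promoters$specificity)
  gtss <- tss(genes)
  nulls <- with_seed(derive_seed(seed, "ep_nulls"), {
    draw <- matched_sampler(obs_cov, pool_cov)
    map_dbl(seq_len(n_sets), function(s) {
      pidx <- draw()
      wd <- sample_matched_values(widths)
      dd <- sample_matched_values(pairs$distance)
      null_prom <- promoters[pidx, , drop = FALSE]
      t0 <- tss(null_prom)
      side <- sample(c(-1, 1), length(pidx), replace = TRUE)
      lens <- setNames(layout$chromosomes$length, layout$chromosomes$chrom)
      len_p <- unname(lens[null_prom$chrom])
      ctr <- t0 + side * dd
      # flip to the other side rather than clamping against a chromosome
      # edge (edge pile-up would bias the matched distances)
      bad <- ctr - wd / 2 < 0 | ctr + wd / 2 > len_p
      ctr[bad] <- (t0 - side * dd)[bad]
      st <- pmax(0, pmin(ctr - wd / 2, len_p - wd))
      null_enh <- tibble(enhancer_id = sprintf("null%05d", seq_along(pidx)),
                         chrom = null_prom$chrom, start = st, end = st + wd,
                         kind = "intergenic")
      null_pairs <- tibble(enhancer_id = null_enh$enhancer_id,
                           gene_id = null_prom$gene_id,
                           distance = abs((null_enh$start + null_enh$end) / 2 - t0))
      chic_support(null_pairs, null_enh, promoters, interactions,
                   min_score, min_distance)$fraction_supported
    })
  })
  nulls[is.na(nulls)] <- 0
  ens <- new_null_ensemble(obs$fraction_supported, nulls, seed,
                           "fraction of E-P pairs with interaction support")
  ens$observed_pairs <- obs$pairs
  ens
}

# Resample each value from its own decile bin of the observed distribution.
sample_matched_values <- function(v) {
  b <- decile_bin(v)
  by_bin <- split(v, b)
  map_dbl(b, function(bb) {
    x <- by_bin[[as.character(bb)]]
    x[sample.int(length(x), 1)]
  })
}

#' Matched-null ensemble for SNP-in-enhancer enrichment
#'
#' Samples `n_sets` background SNP sets of the trait-set size, matched by
#' joint decile bins on the available covariates (`maf`, `gene_density`,
#' `dist_nearest_gene`); the statistic is the number of SNPs falling inside
#' any enhancer region.
#'
#' @param trait_snps,background_snps SNP tibbles with `chrom`, `pos` and the
#'   matching covariates.
#' @param enhancers Enhancer-region tibble.
#' @param n_sets Number of matched sets (default 1,000).
#' @param seed Mandatory RNG seed.
#' @param covariates Covariate columns used for matching.
#' @return A `null_ensemble` of the in-enhancer overlap count.
#' @export
sample_matched_snp_nulls <- function(trait_snps, background_snps, enhancers,
                                     n_sets = 1000, seed,
                                     covariates = c("maf", "gene_density",
                                                    "dist_nearest_gene")) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_sets <= 0) abort("n_sets must be positive")
  if (nrow(trait_snps) == 0) abort("trait SNP set is empty")
  if (nrow(background_snps) < nrow(trait_snps)) {
    abort("background catalog is smaller than the trait set")
  }
  covariates <- intersect(covariates, intersect(names(trait_snps),
                                                names(background_snps)))
  counter <- region_counter(enhancers)
  observed <- sum(counter(trait_snps$chrom, trait_snps$pos))
  bg_hit <- counter(background_snps$chrom, background_snps$pos)
  obs_cov <- trait_snps[, covariates, drop = FALSE]
  pool_cov <- background_snps[, covariates, drop = FALSE]
  nulls <- with_seed(derive_seed(seed, "snp_nulls"), {
    draw <- matched_sampler(obs_cov, pool_cov)
    map_dbl(seq_len(n_sets), function(s) sum(bg_hit[draw()]))
  })
  new_null_ensemble(observed, nulls, seed, "trait SNPs inside enhancers")
}

#' Matched-null enrichment of region-set overlap
#'
#' The statistic is the fraction of query regions intersecting at least one
#' reference region; the null resamples width- and distance-matched random
#' non-coding regions.
#'
#' @param query_regions,reference_regions Interval tibbles.
#' @param layout A [genome_layout()].
#' @param genes Gene tibble (distance-to-promoter covariate).
#' @param n_sets Number of matched sets.
#' @param seed Mandatory RNG seed.
#' @return A `null_ensemble` of the overlap fraction.
#' @export
region_overlap_enrichment <- function(query_regions, reference_regions,
                                      layout, genes, n_sets = 20, seed) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_sets <= 0) abort("n_sets must be positive")
  frac_overlap <- function(q) {
    if (nrow(q) == 0) return(NA_real_)
    mean(suppressWarnings(GenomicRanges::countOverlaps(
      as_granges0(mutate(q, strand = ".")),
      as_granges0(mutate(reference_regions, strand = ".")),
      ignore.strand = TRUE)) > 0)
  }
  observed <- frac_overlap(query_regions)
  widths <- query_regions$end - query_regions$start
  gtss <- tss(genes)
  dist_prom <- map_dbl(seq_len(nrow(query_regions)), function(i) {
    d <- abs(gtss[genes$chrom == query_regions$chrom[i]] -
               (query_regions$start[i] + query_regions$end[i]) / 2)
    if (length(d) == 0) NA_real_ else min(d)
  })
  lens <- setNames(layout$chromosomes$length, layout$chromosomes$chrom)
  nulls <- with_seed(derive_seed(seed, "region_nulls"), {
    map_dbl(seq_len(n_sets), function(s) {
      wd <- sample_matched_values(widths)
      dd <- sample_matched_values(dist_prom)
      gi <- sample.int(nrow(genes), nrow(query_regions), replace = TRUE)
      ctr <- gtss[gi] + sample(c(-1, 1), nrow(query_regions), TRUE) * dd
      ch <- genes$chrom[gi]
      st <- pmax(0, pmin(ctr - wd / 2, lens[ch] - wd))
      frac_overlap(tibble(chrom = ch, start = st, end = st + wd))
    })
  })
  new_null_ensemble(observed, nulls, seed, "fraction of query regions overlapping reference")
}
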