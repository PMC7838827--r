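# Transcription programs: ground-truth activity of genes and enhancers per
# cell line, enhancer-promoter links, replicate depths and noise level.

#' Generate a ground-truth transcription program
#'
#' Draws per-cell-line synthesis rates for every gene and enhancer of a
#' synthetic genome. A configurable fraction of enhancers is exclusively
#' active in a single cell line (one-hot activity); the rest are active in
#' all lines with log-normal line-to-line variation. Enhancers are linked to
#' promoters (intragenic ones to their host gene, intergenic ones to the
#' nearest gene TSS) and linked genes receive activity positively coupled to
#' their enhancer's activity pattern.
#'
#' @param genome A [generate_genome()] result.
#' @param n_cell_lines Number of cell lines (>= 2).
#' @param frac_specific Fraction of enhancers active in exactly one line.
#' @param seed Mandatory RNG seed.
#' @param coupling Coupling coefficient in `[0, 1]` between a linked
#'   enhancer's activity pattern and its gene's.
#' @param frac_linked Fraction of enhancers carrying an E-P link.
#' @param n_replicates Replicates per cell line (depth factors are drawn per
#'   sample = line x replicate).
#' @param gene_rate_meanlog,gene_rate_sdlog Log-normal parameters of the
#'   per-bin gene synthesis rate (counts per 200-bp bin at unit depth).
#' @param enhancer_rate_meanlog,enhancer_rate_sdlog Same for eRNAs.
#' @param line_sdlog Line-to-line log-normal variation of non-specific
#'   features.
#' @param ua_range Range of the per-gene upstream-antisense/sense ratio.
#' @param depth_sdlog Log-normal sd of per-sample depth factors.
#' @param dispersion Log-normal sigma of bin-level noise in
#'   [simulate_coverage()].
#' @return An object of class `truth_program`.
#' @export
generate_programs <- function(genome, n_cell_lines = 14L, frac_specific = 0.37,
                              seed,
                              coupling = 0.8,
                              frac_linked = 0.8,
                              n_replicates = 2L,
                              gene_rate_meanlog = log(12), gene_rate_sdlog = 0.4,
                              enhancer_rate_meanlog = log(9), enhancer_rate_sdlog = 0.3,
                              line_sdlog = 0.5,
                              ua_range = c(0.1, 0.5),
                              depth_sdlog = 0.3,
                              dispersion = 0.3) {
  if (missing(seed)) abort("seed is mandatory")
  if (n_cell_lines < 2) abort("n_cell_lines must be >= 2")
  if (frac_specific < 0 || frac_specific > 1) abort("frac_specific must be in [0, 1]")
  lines <- sprintf("line%02d", seq_len(n_cell_lines))
  genes <- genome$genes
  enh <- genome$enhancers_truth
  ng <- nrow(genes)
  ne <- nrow(enh)
  with_seed(seed, {
    # enhancer activity
    base_e <- rlnorm(ne, enhancer_rate_meanlog, enhancer_rate_sdlog)
    specific <- rep(FALSE, ne)
    if (ne > 0) specific[sample.int(ne, round(frac_specific * ne))] <- TRUE
    ea <- matrix(0, ne, n_cell_lines, dimnames = list(enh$enhancer_id, lines))
    for (i in seq_len(ne)) {
      if (specific[i]) {
        ea[i, sample.int(n_cell_lines, 1)] <- base_e[i]
      } else {
        ea[i, ] <- base_e[i] * rlnorm(n_cell_lines, 0, line_sdlog)
      }
    }
    # E-P links: intragenic -> host gene; intergenic -> nearest gene TSS.
    # Each gene carries at most one link so linked activity profiles are
    # not overwritten by competing enhancers.
    linked <- if (ne > 0) sample.int(ne, round(frac_linked * ne)) else integer(0)
    taken <- character(0)
    links <- list_rbind(map(linked, function(i) {
      gid <- if (!is.na(enh$host_gene[i])) enh$host_gene[i] else {
        same <- genes[genes$chrom == enh$chrom[i], , drop = FALSE]
        mid <- (enh$start[i] + enh$end[i]) / 2
        same$gene_id[which.min(abs(tss(same) - mid))]
      }
      if (gid %in% taken) return(NULL)
      taken <<- c(taken, gid)
      tibble(enhancer_id = enh$enhancer_id[i], gene_id = gid)
    }))
    if (is.null(links) || nrow(links) == 0) {
      links <- tibble(enhancer_id = character(), gene_id = character())
    }
    # gene activity: free genes vary log-normally; linked genes follow their
    # enhancer's pattern with the given coupling
    base_g <- rlnorm(ng, gene_rate_meanlog, gene_rate_sdlog)
    ga <- matrix(0, ng, n_cell_lines, dimnames = list(genes$gene_id, lines))
    for (i in seq_len(ng)) {
      ga[i, ] <- base_g[i] * rlnorm(n_cell_lines, 0, line_sdlog)
    }
    for (k in seq_len(nrow(links))) {
      gi <- match(links$gene_id[k], genes$gene_id)
      ei <- match(links$enhancer_id[k], enh$enhancer_id)
      prof <- ea[ei, ]
      prof <- if (mean(prof) > 0) prof / mean(prof) else rep(1, n_cell_lines)
      ga[gi, ] <- base_g[gi] * ((1 - coupling) * rlnorm(n_cell_lines, 0, line_sdlog) +
                                  coupling * prof)
    }
    ua <- setNames(runif(ng, ua_range[1], ua_range[2]), genes$gene_id)
    samples <- tidyr::expand_grid(line = lines, replicate = seq_len(n_replicates))
    samples$sample <- sprintf("%s_rep%d", samples$line, samples$replicate)
    depth <- setNames(rlnorm(nrow(samples), 0, depth_sdlog), samples$sample)
    # mild per-enhancer strand bias for directionality analyses
    strand_bias <- setNames(rlnorm(ne, 0, 0.3), enh$enhancer_id)
  })
  structure(list(
    lines = lines, samples = samples,
    gene_activity = ga, enhancer_activity = ea,
    ua_fraction = ua, ep_links = links, depth_factor = depth,
    dispersion = dispersion, strand_bias = strand_bias,
    specific = setNames(specific, enh$enhancer_id)
  ), class = "truth_program")
}

#' @export
print.truth_program <- function(x, ...) {
  cat(sprintf(
    "<truth_program> %d cell lines x %d samples, %d genes, %d enhancers (%d one-hot), %d E-P links\n",
    length(x$lines), nrow(x$samples), nrow(x$gene_activity),
    nrow(x$enhancer_activity), sum(x$specific), nrow(x$ep_links)))
  invisible(x)
}

#' Simulate strand-specific binned coverage
#'
#' Draws per-bin fragment-midpoint counts from a Poisson-log-normal model:
#' `count ~ Poisson(lambda * exp(sigma * Z))`, `Z ~ N(0, 1)`, where `lambda`
#' is the sample depth factor times the local synthesis rate. Active genes
#' produce sense-strand signal over the gene body and antisense signal in
#' the upstream-antisense window (TSS-150 to TSS-1,150); intergenic
#' enhancer states produce divergent bidirectional signal and intragenic
#' states antisense-only signal over their planted eRNAs; everywhere else a
#' uniform background rate applies. With `noise = FALSE` bins carry the
#' rounded expected rate instead (deterministic, unit depth).
#'
#' @param genome A [generate_genome()] result.
#' @param truth A [generate_programs()] result.
#' @param seed Mandatory RNG seed (ignored when `noise = FALSE`).
#' @param samples Subset of sample ids to simulate (default: all).
#' @param background Background rate per bin.
#' @param noise Draw Poisson-log-normal noise? `FALSE` gives noise-free
#'   expected coverage at unit depth.
#' @return Named list of [binned_coverage()] objects, one per sample.
#' @export
simulate_coverage <- function(genome, truth, seed, samples = NULL,
                              background = 0.05, noise = TRUE) {
  if (missing(seed)) {
    if (noise) abort("seed is mandatory when noise = TRUE") else seed <- 0L
  }
  layout <- genome$layout
  w <- layout$bin_width
  sm <- truth$samples
  if (!is.null(samples)) sm <- sm[sm$sample %in% samples, , drop = FALSE]

  rate_tracks <- function(line) {
    plus <- map(setNames(nm = layout$chromosomes$chrom),
                function(ch) rep(background, n_bins(layout, ch)))
    minus <- plus
    add <- function(track, ch, start, end, rate) {
      if (end <= start) return(track)
      # weight partial bins by overlap fraction
      b0 <- floor(start / w)
      b1 <- ceiling(end / w) - 1
      idx <- seq.int(b0, b1)
      lo <- pmax(start, idx * w)
      hi <- pmin(end, (idx + 1) * w)
      track[[ch]][idx + 1L] <- track[[ch]][idx + 1L] + rate * (hi - lo) / w
      track
    }
    g <- genome$genes
    act <- truth$gene_activity[, line]
    for (i in seq_len(nrow(g))) {
      a <- act[g$gene_id[i]]
      if (a <= 0) next
      if (g$strand[i] == "+") {
        plus <- add(plus, g$chrom[i], g$start[i], g$end[i], a)
        ua0 <- max(0, g$start[i] - 1150)
        minus <- add(minus, g$chrom[i], ua0, g$start[i] - 150, a * truth$ua_fraction[g$gene_id[i]])
      } else {
        minus <- add(minus, g$chrom[i], g$start[i], g$end[i], a)
        plus <- add(plus, g$chrom[i], g$end[i] + 150, g$end[i] + 1150, a * truth$ua_fraction[g$gene_id[i]])
      }
    }
    er <- genome$ernas_truth
    eact <- truth$enhancer_activity[, line]
    for (i in seq_len(nrow(er))) {
      a <- eact[er$enhancer_id[i]]
      if (a <= 0) next
      bias <- truth$strand_bias[er$enhancer_id[i]]
      a <- a * if (er$strand[i] == "+") bias else 1 / bias
      if (er$strand[i] == "+") {
        plus <- add(plus, er$chrom[i], er$start[i], er$end[i], a)
      } else {
        minus <- add(minus, er$chrom[i], er$start[i], er$end[i], a)
      }
    }
    list(plus = plus, minus = minus)
  }

  rates_by_line <- map(setNames(nm = unique(sm$line)), rate_tracks)
  out <- list()
  for (k in seq_len(nrow(sm))) {
    s <- sm$sample[k]
    r <- rates_by_line[[sm$line[k]]]
    draw <- function(vec, label) {
      if (!noise) return(as.integer(round(vec)))
      lam <- vec * truth$depth_factor[s]
      with_seed(derive_seed(seed, label), {
        as.integer(rpois(length(lam), lam * exp(truth$dispersion * rnorm(length(lam)))))
      })
    }
    out[[s]] <- binned_coverage(
      s, layout,
      plus = imap(r$plus, function(v, ch) draw(v, paste(s, "+", ch))),
      minus = imap(r$minus, function(v, ch) draw(v, paste(s, "-", ch))))
  }
  out
}
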