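# Transcription directionality at promoters and enhancers, entropy and
# Jensen-Shannon cell-type specificity scores, and cross-cell-line
# correlation of transcription patterns.

#' Promoter transcription directionality
#'
#' For every eligible protein-coding promoter (no opposite-strand coding
#' gene within +- 5 kbp of the sense TSS), counts normalized fragments in
#' the sense window (TSS to TSS + 1,000 bp) and the upstream antisense
#' window (TSS - 1,150 to TSS - 150 bp), both strand-mirrored for minus
#' genes. A promoter is bidirectional iff both windows reach `min_counts`
#' normalized counts; the directionality score is the sense/antisense
#' ratio, reported for bidirectional promoters only.
#'
#' @param genes Protein-coding gene tibble.
#' @param coverage A [binned_coverage()] for the cell line.
#' @param size_factor Scalar size factor for normalization.
#' @param min_counts Minimal normalized count on each strand (default 10).
#' @param exclusion_radius Radius of the opposite-strand coding-gene
#'   exclusion, bp.
#' @return Tibble: `gene_id`, `sense`, `antisense` (normalized counts),
#'   `bidirectional`, `ratio` (NA unless bidirectional).
#' @export
promoter_directionality <- function(genes, coverage, size_factor = 1,
                                    min_counts = 10, exclusion_radius = 5000) {
  if ("biotype" %in% names(genes)) genes <- filter(genes, .data$biotype == "protein_coding")
  gtss <- tss(genes)
  eligible <- map_lgl_(seq_len(nrow(genes)), function(i) {
    opp <- genes$strand != genes$strand[i] & genes$chrom == genes$chrom[i]
    !any(opp & abs(gtss - gtss[i]) <= exclusion_radius)
  })
  g <- genes[eligible, , drop = FALSE]
  t0 <- gtss[eligible]
  sense_win <- tibble(chrom = g$chrom,
                      start = ifelse(g$strand == "+", t0, t0 - 1000),
                      end = ifelse(g$strand == "+", t0 + 1000, t0),
                      strand = g$strand)
  anti_win <- tibble(chrom = g$chrom,
                     start = ifelse(g$strand == "+", t0 - 1150, t0 + 150),
                     end = ifelse(g$strand == "+", t0 - 150, t0 + 1150),
                     strand = g$strand)
  sense_win$start <- pmax(0, sense_win$start)
  anti_win$start <- pmax(0, anti_win$start)
  sense <- count_fragments(sense_win, coverage, "sense") / size_factor
  anti <- count_fragments(anti_win, coverage, "antisense") / size_factor
  bidir <- sense >= min_counts & anti >= min_counts
  tibble(gene_id = g$gene_id, sense = sense, antisense = anti,
         bidirectional = bidir,
         ratio = ifelse(bidir, sense / anti, NA_real_))
}

#' Enhancer transcription directionality
#'
#' For bidirectional intergenic enhancer regions shorter than `max_width`,
#' the score is the ratio of plus- to minus-strand normalized counts
#' (relative to the reference plus strand). Regions with ratio >= `cutoff`
#' or <= 1/`cutoff` show a preferred direction; the rest are balanced.
#'
#' @param regions Enhancer-region tibble (intergenic).
#' @param coverage A [binned_coverage()].
#' @param size_factor Scalar size factor.
#' @param max_width Strict width bound for inclusion (default 3,000 bp).
#' @param cutoff Ratio threshold separating preferred from balanced.
#' @return Tibble with `plus`, `minus`, `ratio`, `category`.
#' @export
enhancer_directionality <- function(regions, coverage, size_factor = 1,
                                    max_width = 3000, cutoff = 3) {
  r <- filter(regions, .data$kind == "intergenic",
              .data$end - .data$start < max_width)
  if (nrow(r) == 0) {
    return(tibble(enhancer_id = character(), plus = numeric(),
                  minus = numeric(), ratio = numeric(), category = character()))
  }
  q <- mutate(r, strand = "+")
  plus <- count_fragments(q, coverage, "sense") / size_factor
  minus <- count_fragments(q, coverage, "antisense") / size_factor
  ratio <- ifelse(minus > 0, plus / minus, NA_real_)
  id_col <- if ("merged_id" %in% names(r)) r$merged_id else r$enhancer_id
  tibble(enhancer_id = id_col, plus = plus, minus = minus, ratio = ratio,
         category = case_when(
           is.na(ratio) ~ NA_character_,
           ratio >= cutoff | ratio <= 1 / cutoff ~ "preferred",
           TRUE ~ "balanced"))
}

shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Entropy-based overall cell-type specificity
#'
#' `1 - H(p) / log2(n)` where `p` is the activity vector normalized to a
#' probability distribution and `H` its Shannon entropy in bits (with the
#' 0 log 0 = 0 convention). 0 means uniform activity across all cell
#' lines; 1 means activity confined to a single line.
#'
#' @param x Nonnegative activity vector over `n >= 2` cell lines.
#' @return Scalar in `[0, 1]`, or `NA` when `sum(x) == 0`.
#' @export
entropy_specificity <- function(x) {
  if (any(x < 0)) abort("activities must be nonnegative")
  n <- length(x)
  if (n < 2) abort("need at least 2 cell lines")
  s <- sum(x)
  if (s == 0) return(NA_real_)
  1 - shannon_entropy(x / s) / log2(n)
}

#' Jensen-Shannon cell-line specificity
#'
#' Normalizes the transcription pattern `t` to a probability vector,
#' computes the JS divergence (in bits) between it and the indicator
#' pattern of cell line `c`, and returns `1 - sqrt(JS)`. The square root of
#' the JS divergence is a metric, so the score is 1 exactly when the
#' pattern is synthesized only in line `c` and 0 when it is confined to a
#' different single line.
#'
#' @param t Nonnegative transcription pattern over cell lines.
#' @param c Index of the reference cell line.
#' @return Scalar in `[0, 1]`, or `NA` when `sum(t) == 0`.
#' @export
js_specificity <- function(t, c) {
  if (any(t < 0)) abort("activities must be nonnegative")
  stopifnot(length(c) == 1, c >= 1, c <= length(t))
  s <- sum(t)
  if (s == 0) return(NA_real_)
  p1 <- t / s
  p2 <- numeric(length(t))
  p2[c] <- 1
  js <- shannon_entropy((p1 + p2) / 2) - (shannon_entropy(p1) + shannon_entropy(p2)) / 2
  js <- min(max(js, 0), 1)                      # guard tiny negative rounding
  1 - sqrt(js)
}

#' Specificity scores for every row of an activity matrix
#'
#' @param activity Feature-by-cell-line matrix of replicate-averaged FPK.
#' @return Tibble with `feature`, `specificity` (entropy-based overall
#'   score), `js_best_line` and `js_best` (the cell line maximizing the JS
#'   score and its value).
#' @export
specificity_scores <- function(activity) {
  lines <- colnames(activity)
  out <- map(seq_len(nrow(activity)), function(i) {
    x <- activity[i, ]
    if (sum(x) == 0) {
      return(tibble(specificity = NA_real_, js_best_line = NA_character_,
                    js_best = NA_real_))
    }
    jss <- map_dbl(seq_along(x), function(cc) js_specificity(x, cc))
    best <- which.max(jss)
    tibble(specificity = entropy_specificity(x),
           js_best_line = lines[best], js_best = jss[best])
  })
  bind_cols(tibble(feature = rownames(activity)), list_rbind(out))
}

#' Cross-cell-line correlation of two transcription patterns
#'
#' For matched feature pairs (rows of `matrix_a` and `matrix_b` over the
#' same cell lines), keeps features with bidirectional observation (both
#' entries at least `min_counts`) in at least `min_lines` lines and
#' coefficient of variation above `min_cv` in both vectors, then reports
#' the Pearson correlation of `log2(count)` across the qualifying lines.
#'
#' @param matrix_a,matrix_b Feature-by-cell-line matrices with identical
#'   dimensions (e.g., mRNA and uaRNA counts, or plus and minus strand
#'   counts).
#' @param min_lines Minimal number of qualifying cell lines (default 5).
#' @param min_cv Minimal coefficient of variation (default 0.5).
#' @param min_counts Minimal count for an observation to qualify.
#' @return Tibble: `feature`, `n_lines`, `r` (one row per retained feature).
#' @export
cross_line_correlation <- function(matrix_a, matrix_b, min_lines = 5,
                                   min_cv = 0.5, min_counts = 10) {
  stopifnot(all(dim(matrix_a) == dim(matrix_b)))
  out <- list()
  for (i in seq_len(nrow(matrix_a))) {
    a <- matrix_a[i, ]
    b <- matrix_b[i, ]
    ok <- a >= min_counts & b >= min_counts
    if (sum(ok) < min_lines) next
    cva <- coef_var(a[ok])
    cvb <- coef_var(b[ok])
    if (is.na(cva) || is.na(cvb) || cva <= min_cv || cvb <= min_cv) next
    la <- log2(a[ok])
    lb <- log2(b[ok])
    if (stats::sd(la) == 0 || stats::sd(lb) == 0) next
    out[[length(out) + 1]] <- tibble(
      feature = rownames(matrix_a)[i] %||% as.character(i),
      n_lines = sum(ok), r = cor(la, lb))
  }
  if (length(out) == 0) {
    return(tibble(feature = character(), n_lines = integer(), r = numeric()))
  }
  list_rbind(out)
}
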