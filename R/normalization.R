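# Median-of-ratios size factors and length-normalized activity (FPK).

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features of the
#' ratio of the feature's count to its geometric mean across samples.
#' Features with a zero count in any sample are excluded from the median
#' (their geometric-mean ratio is not informative).
#'
#' @param counts Feature-by-sample matrix (or data frame) of nonnegative
#'   integer counts; rows are features, columns samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) abort("size_factors needs >= 2 samples")
  if (any(counts < 0)) abort("counts must be nonnegative")
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) abort("no feature has nonzero counts in all samples")
  lk <- log(counts[keep, , drop = FALSE])
  geo <- rowMeans(lk)
  s <- apply(lk, 2, function(col) exp(stats::median(col - geo)))
  gm <- exp(mean(log(s)))
  if (gm < 0.5 || gm > 2) {
    warn(sprintf("geometric mean of size factors is %.3g; counts may be ill-behaved", gm))
  }
  s
}

#' Length-normalized activity (FPK)
#'
#' `FPK = (count / size_factor) / (length / 1000)` — fragments per kilobase
#' of feature after depth normalization. Returns both the per-sample FPK
#' matrix and, when a sample-to-cell-line map is given, the
#' replicate-averaged (arithmetic mean) per-line matrix.
#'
#' @param counts Feature-by-sample count matrix.
#' @param size_factors Named size factors, one per column of `counts`.
#' @param effective_lengths Positive effective lengths in bp, one per row.
#' @param sample_lines Optional named character vector mapping sample ->
#'   cell line for replicate averaging.
#' @return A list of class `activity_matrix`: `fpk` (per sample), `by_line`
#'   (replicate-averaged, or NULL), `effective_lengths`.
#' @export
fpk <- function(counts, size_factors, effective_lengths, sample_lines = NULL) {
  counts <- as.matrix(counts)
  if (any(effective_lengths <= 0)) abort("effective lengths must be > 0")
  stopifnot(length(effective_lengths) == nrow(counts),
            length(size_factors) == ncol(counts))
  x <- sweep(counts, 2, size_factors, "/")
  x <- sweep(x, 1, effective_lengths / 1000, "/")
  by_line <- NULL
  if (!is.null(sample_lines)) {
    sl <- sample_lines[colnames(counts)]
    by_line <- sapply(unique(sl), function(l) {
      rowMeans(x[, sl == l, drop = FALSE])
    })
    if (is.null(dim(by_line))) by_line <- matrix(by_line, nrow = nrow(x),
                                                 dimnames = list(rownames(x), unique(sl)))
  }
  structure(list(fpk = x, by_line = by_line,
                 effective_lengths = effective_lengths),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix> %d features x %d samples%s\n",
              nrow(x$fpk), ncol(x$fpk),
              if (!is.null(x$by_line)) sprintf(" (%d cell lines)", ncol(x$by_line)) else ""))
  invisible(x)
}

#' @describeIn fpk Long tidy view of the per-sample FPK matrix.
#' @param x An `activity_matrix`.
#' @param ... Unused.
#' @export
as_tibble.activity_matrix <- function(x, ...) {
  m <- x$fpk
  tibble(feature = rep(rownames(m), ncol(m)),
         sample = rep(colnames(m), each = nrow(m)),
         fpk = as.vector(m))
}

#' Expression-based activity call
#'
#' A feature is active in a cell line iff its replicate-averaged FPK is at
#' least `threshold_mean` and every replicate reaches
#' `threshold_per_replicate`.
#'
#' @param activity An [fpk()] result with a `by_line` component.
#' @param sample_lines Named character vector mapping sample -> cell line.
#' @param threshold_mean Mean-FPK activity cutoff (default 20).
#' @param threshold_per_replicate Per-replicate FPK floor (default 15).
#' @return Logical feature-by-cell-line matrix.
#' @export
classify_active <- function(activity, sample_lines,
                            threshold_mean = 20, threshold_per_replicate = 15) {
  stopifnot(inherits(activity, "activity_matrix"))
  x <- activity$fpk
  sl <- sample_lines[colnames(x)]
  lines <- unique(sl)
  out <- sapply(lines, function(l) {
    sub <- x[, sl == l, drop = FALSE]
    rowMeans(sub) >= threshold_mean &
      apply(sub, 1, function(r) all(r >= threshold_per_replicate))
  })
  if (is.null(dim(out))) out <- matrix(out, ncol = length(lines),
                                       dimnames = list(rownames(x), lines))
  colnames(out) <- lines
  out
}

#' Density-valley diagnostic for the expression cutoff
#'
#' Optional diagnostic reproducing how a global FPK cutoff can be read off
#' the bimodal distribution of `log2(FPK)` over genes: returns the location
#' of the density valley between the two modes. The pipeline default stays
#' at the fixed FPK >= 20 cutoff.
#'
#' @param fpk_values Positive FPK values over genes (zeros dropped).
#' @return The valley position on the FPK scale (or NA if unimodal).
#' @export
fpk_valley_cutoff <- function(fpk_values) {
  v <- log2(fpk_values[fpk_values > 0])
  if (length(v) < 10) return(NA_real_)
  d <- stats::density(v)
  y <- d$y
  # interior local minima
  mins <- which(diff(sign(diff(y))) == 2) + 1L
  maxs <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(maxs) < 2 || length(mins) < 1) return(NA_real_)
  top2 <- maxs[order(y[maxs], decreasing = TRUE)[1:2]]
  valley <- mins[mins > min(top2) & mins < max(top2)]
  if (length(valley) == 0) return(NA_real_)
  2 ^ d$x[valley[which.min(y[valley])]]
}
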