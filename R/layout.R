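#' Genome layout: chromosome sizes and the binning grid
#'
#' The coordinate frame for the whole pipeline: a set of chromosomes and a
#' fixed bin width (default 200 bp). Strand-specific coverage is stored as
#' fragment-midpoint counts in consecutive bins of this width.
#'
#' @param chromosomes A data frame with columns `chrom` (unique names) and
#'   `length` (bp, each a positive multiple of `bin_width`).
#' @param bin_width Bin width in bp.
#' @return An object of class `genome_layout`.
#' @examples
#' genome_layout(tibble::tibble(chrom = "chr1", length = 1e6))
#' @export
genome_layout <- function(chromosomes, bin_width = 200L) {
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$chrom)) abort("chromosome names must be unique")
  if (any(chromosomes$length <= 0)) abort("chromosome lengths must be > 0")
  if (any(chromosomes$length %% bin_width != 0)) {
    abort("chromosome lengths must be multiples of bin_width")
  }
  structure(
    list(chromosomes = chromosomes, bin_width = as.integer(bin_width)),
    class = "genome_layout"
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosome(s), %.3g Mbp total, %d-bp bins\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6, x$bin_width))
  invisible(x)
}

n_bins <- function(layout, chrom) {
  len <- layout$chromosomes$length[match(chrom, layout$chromosomes$chrom)]
  if (anyNA(len)) abort(sprintf("unknown chromosome: %s",
                                paste(chrom[is.na(len)], collapse = ", ")))
  as.integer(ceiling(len / layout$bin_width))
}

#' Strand-specific binned coverage for one sample
#'
#' Container for fragment-midpoint counts in consecutive fixed-width bins,
#' one integer vector per chromosome and strand.
#'
#' @param sample_id Sample identifier.
#' @param layout A [genome_layout()].
#' @param plus,minus Named lists (by chromosome) of nonnegative integer
#'   count vectors, one entry per bin.
#' @return An object of class `binned_coverage`.
#' @export
binned_coverage <- function(sample_id, layout, plus, minus) {
  stopifnot(inherits(layout, "genome_layout"))
  for (str in list(plus, minus)) {
    stopifnot(is.list(str))
    for (ch in names(str)) {
      if (length(str[[ch]]) != n_bins(layout, ch)) {
        abort(sprintf("coverage vector length for %s must be %d", ch, n_bins(layout, ch)))
      }
      if (any(str[[ch]] < 0)) abort("counts must be nonnegative")
    }
  }
  structure(list(sample_id = sample_id, layout = layout,
                 plus = plus, minus = minus),
            class = "binned_coverage")
}

#' @export
print.binned_coverage <- function(x, ...) {
  tot <- sum(map_dbl(x$plus, sum)) + sum(map_dbl(x$minus, sum))
  cat(sprintf("<binned_coverage> sample %s, %d-bp bins, %.4g fragments\n",
              x$sample_id, x$layout$bin_width, tot))
  invisible(x)
}

#' @describeIn binned_coverage Long-format view: one row per nonzero bin
#'   (`chrom`, `start`, `end`, `strand`, `count`, `sample`).
#' @param x A `binned_coverage`.
#' @param ... Unused.
#' @export
as_tibble.binned_coverage <- function(x, ...) {
  w <- x$layout$bin_width
  one_strand <- function(vecs, strand) {
    list_rbind(imap(vecs, function(v, ch) {
      nz <- which(v != 0)
      tibble(chrom = ch, start = (nz - 1L) * w, end = nz * w,
             strand = strand, count = as.numeric(v[nz]))
    }))
  }
  out <- bind_rows(one_strand(x$plus, "+"), one_strand(x$minus, "-"))
  out$sample <- x$sample_id
  out
}

#' Pool several coverage objects by summing bins
#'
#' Used to pool replicates of one cell line before segmentation.
#'
#' @param covs A list of [binned_coverage()] objects on the same layout.
#' @param sample_id Identifier for the pooled sample.
#' @return A [binned_coverage()].
#' @export
pool_coverage <- function(covs, sample_id = "pooled") {
  stopifnot(length(covs) >= 1)
  out <- covs[[1]]
  if (length(covs) > 1) {
    for (i in 2:length(covs)) {
      for (ch in names(out$plus)) out$plus[[ch]] <- out$plus[[ch]] + covs[[i]]$plus[[ch]]
      for (ch in names(out$minus)) out$minus[[ch]] <- out$minus[[ch]] + covs[[i]]$minus[[ch]]
    }
  }
  out$sample_id <- sample_id
  out
}
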