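# Reading/writing standard genomic formats and interval counting primitives.
# rtracklayer does the format heavy lifting; everything user-facing is a
# 0-based half-open tibble.

#' Read a GTF or BED annotation into a tidy interval table
#'
#' Coordinates are converted to the internal 0-based half-open convention
#' (GTF is 1-based closed on disk; BED is already 0-based half-open). For
#' GTF, only `gene` and `exon` features are retained, with `gene_id` and
#' `biotype` (from `gene_biotype`/`gene_type` when present).
#'
#' @param path File path.
#' @param dialect `"gtf"` or `"bed"`.
#' @return A tibble with columns `chrom`, `start`, `end`, `strand` and, for
#'   GTF, `feature`, `gene_id`, `biotype`.
#' @export
read_annotation <- function(path, dialect = c("gtf", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (file.size(path) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  strand = character()))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "bed"),
    error = function(e) abort(sprintf("malformed %s file %s: %s", dialect, path,
                                      conditionMessage(e)))
  )
  out <- granges_to_tibble(gr)
  md <- as_tibble(as.data.frame(S4Vectors::mcols(gr)))
  if (dialect == "gtf") {
    if ("type" %in% names(md)) out$feature <- as.character(md$type)
    if ("gene_id" %in% names(md)) out$gene_id <- as.character(md$gene_id)
    bt <- intersect(c("biotype", "gene_biotype", "gene_type"), names(md))
    out$biotype <- if (length(bt) > 0) as.character(md[[bt[1]]]) else NA_character_
    out <- filter(out, .data$feature %in% c("gene", "exon"))
  } else {
    if ("name" %in% names(md)) out$name <- as.character(md$name)
    if ("score" %in% names(md)) out$score <- as.numeric(md$score)
  }
  out
}

#' Bin fragments by their midpoints
#'
#' Each fragment increments exactly one bin: the bin containing
#' `floor((start + end) / 2)`. Strands are kept separate.
#'
#' @param fragments A tibble with `chrom`, `start`, `end`, `strand`.
#' @param layout A [genome_layout()].
#' @param sample_id Sample identifier for the result.
#' @return A [binned_coverage()].
#' @export
bin_midpoints <- function(fragments, layout, sample_id = "sample") {
  assert_intervals(fragments, "fragments")
  lens <- setNames(layout$chromosomes$length, layout$chromosomes$chrom)
  if (nrow(fragments) > 0) {
    bad <- is.na(match(fragments$chrom, names(lens)))
    if (any(bad)) abort(sprintf("unknown chromosome: %s", fragments$chrom[which(bad)[1]]))
    if (any(fragments$start < 0 | fragments$end > lens[fragments$chrom])) {
      abort("fragment outside chromosome bounds")
    }
  }
  w <- layout$bin_width
  empty <- map(setNames(nm = names(lens)), function(ch) integer(n_bins(layout, ch)))
  plus <- empty
  minus <- empty
  if (nrow(fragments) > 0) {
    mid <- floor((fragments$start + fragments$end) / 2)
    bin <- floor(mid / w) + 1L
    for (str in c("+", "-")) {
      sel <- fragments$strand == str
      tb <- table(fragments$chrom[sel], bin[sel])
      for (ch in rownames(tb)) {
        idx <- as.integer(colnames(tb))
        v <- if (str == "+") plus[[ch]] else minus[[ch]]
        v[idx] <- v[idx] + as.integer(tb[ch, ])
        if (str == "+") plus[[ch]] <- v else minus[[ch]] <- v
      }
    }
  }
  binned_coverage(sample_id, layout, plus, minus)
}

# Indices of bins whose midpoint falls inside [start, end).
bins_in_interval <- function(start, end, w) {
  i_min <- ceiling((start - w / 2) / w)       # 0-based bin index
  i_max <- ceiling((end - w / 2) / w) - 1
  if (i_max < i_min) return(integer(0))
  seq.int(i_min, i_max) + 1L                  # 1-based vector index
}

#' Count binned fragments over intervals
#'
#' The count for an interval is the sum over bins whose midpoints lie in the
#' interval, on the strand selected by `strand_rule` relative to the
#' interval's own strand (unstranded intervals treat `"+"` as sense).
#'
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally `strand`.
#' @param coverage A [binned_coverage()].
#' @param strand_rule `"sense"`, `"antisense"`, or `"both"`.
#' @return Numeric vector of counts, one per interval row.
#' @export
count_fragments <- function(intervals, coverage,
                            strand_rule = c("sense", "antisense", "both")) {
  strand_rule <- match.arg(strand_rule)
  assert_intervals(intervals)
  w <- coverage$layout$bin_width
  strand <- if ("strand" %in% names(intervals)) intervals$strand else rep("+", nrow(intervals))
  strand[is.na(strand) | strand == "."] <- "+"
  n <- nrow(intervals)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- bins_in_interval(intervals$start[i], intervals$end[i], w)
    if (length(idx) == 0) next
    ch <- intervals$chrom[i]
    sense_vec <- if (strand[i] == "+") coverage$plus[[ch]] else coverage$minus[[ch]]
    anti_vec <- if (strand[i] == "+") coverage$minus[[ch]] else coverage$plus[[ch]]
    idx <- idx[idx >= 1 & idx <= length(sense_vec)]
    out[i] <- switch(strand_rule,
      sense = sum(sense_vec[idx]),
      antisense = sum(anti_vec[idx]),
      both = sum(sense_vec[idx]) + sum(anti_vec[idx])
    )
  }
  out
}

#' Write coverage or intervals to a track file
#'
#' `bedgraph` writes one strand of a [binned_coverage()] (nonzero bins only);
#' `bed` writes an interval tibble as BED6. Round-trips with the matching
#' reader are lossless for integer counts.
#'
#' @param x A [binned_coverage()] (for bedgraph) or interval tibble (for bed).
#' @param path Output file.
#' @param dialect `"bedgraph"` or `"bed"`.
#' @param strand For bedgraph: which strand to write (`"+"` or `"-"`).
#' @return `path`, invisibly.
#' @export
write_track <- function(x, path, dialect = c("bedgraph", "bed"), strand = "+") {
  dialect <- match.arg(dialect)
  if (dialect == "bedgraph") {
    stopifnot(inherits(x, "binned_coverage"))
    df <- as_tibble(x)
    df <- df[df$strand == strand, , drop = FALSE]
    gr <- GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1L, df$end),
                                 score = df$count)
    rtracklayer::export(gr, path, format = "bedGraph")
  } else {
    assert_intervals(x)
    gr <- as_granges0(x)
    if ("name" %in% names(x)) gr$name <- x$name
    if ("score" %in% names(x)) gr$score <- x$score
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read a bedGraph track back into per-bin counts for one strand
#'
#' @param path bedGraph file written by [write_track()] (or compatible).
#' @param layout A [genome_layout()] giving the binning grid.
#' @return A named list (by chromosome) of per-bin count vectors.
#' @export
read_bedgraph_bins <- function(path, layout) {
  out <- map(setNames(nm = layout$chromosomes$chrom),
             function(ch) numeric(n_bins(layout, ch)))
  if (file.size(path) == 0) return(out)
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- granges_to_tibble(gr)
  df$score <- gr$score
  w <- layout$bin_width
  for (i in seq_len(nrow(df))) {
    ch <- df$chrom[i]
    idx <- (df$start[i] %/% w + 1L):((df$end[i] - 1L) %/% w + 1L)
    out[[ch]][idx] <- out[[ch]][idx] + df$score[i]
  }
  out
}
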