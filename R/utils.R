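# Internal helpers shared across modules. All genomic coordinates inside the
# package are 0-based half-open; BED stays as-is on IO, GTF is shifted.

# Evaluate `code` with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a parent seed and a stream label; keeps every
# stage's randomness an explicit pure function of (seed, stage).
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * (seq_along(utf8ToInt(label)) %% 31L + 1L))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}

#' Strand-aware 5' end (TSS) of intervals
#'
#' For a 0-based half-open interval the TSS is `start` on the plus strand and
#' `end` on the minus strand.
#'
#' @param x A data frame with `start`, `end`, `strand` columns.
#' @return Numeric vector of TSS coordinates.
#' @export
tss <- function(x) {
  ifelse(x$strand == "-", x$end, x$start)
}

# Strand-aware 3' end.
tes <- function(x) {
  ifelse(x$strand == "-", x$start, x$end)
}

assert_intervals <- function(x, name = "intervals") {
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("%s must have columns %s (missing: %s)", name,
                  paste(need, collapse = ", "), paste(miss, collapse = ", ")))
  }
  if (nrow(x) > 0 && any(x$start < 0 | x$end <= x$start)) {
    abort(sprintf("%s must satisfy 0 <= start < end", name))
  }
  invisible(x)
}

# Convert a 0-based half-open interval tibble to GRanges (1-based closed).
as_granges0 <- function(x) {
  assert_intervals(x)
  strand <- if ("strand" %in% names(x)) x$strand else "*"
  strand[is.na(strand) | strand == "."] <- "*"
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand
  )
}

# GRanges back to a 0-based tibble.
granges_to_tibble <- function(gr) {
  tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = {
      s <- as.character(GenomicRanges::strand(gr))
      s[s == "*"] <- "."
      s
    }
  )
}

# Deterministic content hash (used for reproducibility audits and logs).
content_hash <- function(x) rlang::hash(x)

# Coefficient of variation of a nonnegative vector.
coef_var <- function(x) {
  m <- mean(x)
  if (m == 0) return(NA_real_)
  stats::sd(x) / m
}

# Decile bin index (1..10) of x within reference values; constant vectors
# collapse to bin 1.
decile_bin <- function(x, ref = x) {
  br <- unique(stats::quantile(ref, probs = seq(0, 1, 0.1), na.rm = TRUE, names = FALSE))
  if (length(br) < 2) return(rep(1L, length(x)))
  x <- pmin(pmax(x, br[1]), br[length(br)])   # clamp outside-range values
  x[is.na(x)] <- br[1]
  as.integer(cut(x, breaks = br, include.lowest = TRUE, labels = FALSE))
}
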