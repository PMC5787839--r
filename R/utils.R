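## Internal helpers shared across modules.

CONTEXTS <- c("CG", "CHG", "CHH")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Deterministic child seed from (seed, ...integer tags), kept below 2^31.
## Doubles are exact up to 2^53 so the modular arithmetic is exact.
derive_seed <- function(seed, ...) {
  tags <- c(...)
  s <- as.numeric(seed) %% 2147483647
  for (t in tags) {
    s <- (s * 69069 + as.numeric(t) * 7919 + 1) %% 2147483647
  }
  as.integer(s)
}

## Evaluate expr under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Validate a scalar probability.
check_prob <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(what, " must be a single probability in [0, 1]", call. = FALSE)
  invisible(x)
}

## chrom column as factor in genome order, for deterministic sorting.
order_by_genome <- function(dt, chrom_order) {
  dt[order(factor(chrom, levels = chrom_order), pos)]
}

## Pooled (count-weighted) methylation level; NA when uncovered.
pooled_ml <- function(meth, unmeth) {
  tot <- meth + unmeth
  ifelse(tot > 0, meth / tot, NA_real_)
}

## Quartiles by linear interpolation of (n+1)p order statistics
## (quantile type 6) plus 1.5*IQR whiskers.
boxplot_stats <- function(x, qtype = 6) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) {
    return(list(n = 0L, q1 = NA_real_, median = NA_real_, q3 = NA_real_,
                whisker_lo = NA_real_, whisker_hi = NA_real_))
  }
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), type = qtype, names = FALSE)
  iqr <- qs[3] - qs[1]
  lo <- x[x >= qs[1] - 1.5 * iqr]
  hi <- x[x <= qs[3] + 1.5 * iqr]
  list(n = length(x), q1 = qs[1], median = qs[2], q3 = qs[3],
       whisker_lo = min(lo), whisker_hi = max(hi))
}

## GRanges from a data.table-like with chrom/start/end (1-based inclusive).
ranges_of <- function(x, strand = NULL) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start, end = x$end),
    strand = if (is.null(strand)) "*" else strand
  )
}

## GRanges of single positions.
site_ranges <- function(dt) {
  GenomicRanges::GRanges(dt$chrom, IRanges::IRanges(dt$pos, dt$pos))
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}
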