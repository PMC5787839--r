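## Sliding-window methylation summaries.

#' Sliding-window start/end positions for one chromosome
#'
#' Windows start at 1, 1+step, ... All windows that fit entirely on the
#' chromosome are emitted. A single trailing truncated window (starting one
#' step after the last full window and ending at the chromosome end) is
#' added only when the chromosome extends beyond the last full window's end
#' by at least half a window; shorter leftovers are dropped as
#' high-variance slivers. A chromosome shorter than one window yields a
#' single truncated window when it is at least half a window long.
#'
#' @param L chromosome length (bp).
#' @param window_size window width in bp.
#' @param step step size in bp; must divide `window_size`.
#' @return `data.table` with `start`, `end` (1-based inclusive).
#' @export
window_starts <- function(L, window_size, step) {
  stopifnot(L >= 1, window_size >= 1, step >= 1)
  if (window_size %% step != 0L)
    stop("window_size must be a multiple of step", call. = FALSE)
  if (L >= window_size) {
    n_full <- (L - window_size) %/% step + 1L
    starts <- 1L + step * (seq_len(n_full) - 1L)
    ends <- starts + window_size - 1L
    last_end <- ends[n_full]
    if (L - last_end >= window_size / 2) {
      starts <- c(starts, starts[n_full] + step)
      ends <- c(ends, L)
    }
    data.table::data.table(start = as.integer(starts), end = as.integer(ends))
  } else if (L >= window_size / 2) {
    data.table::data.table(start = 1L, end = as.integer(L))
  } else {
    data.table::data.table(start = integer(), end = integer())
  }
}

#' Summarize methylation in sliding windows
#'
#' Methylated and unmethylated read counts of covered sites are summed per
#' window and context; the window methylation level is the count-pooled
#' (weighted) level sum(meth)/sum(meth+unmeth), never the mean of per-site
#' levels. Windows with no covered sites of a context are flagged undefined
#' (`ml = NA`).
#'
#' @param sm `site_methylation` table ([compute_site_methylation()]).
#' @param chrom_len named vector of chromosome lengths
#'   (see [chrom_lengths()]).
#' @param window_size window width in bp (default 3000).
#' @param step step size in bp (default 600).
#' @param correct apply the nonconversion correction (with the `r` stored on
#'   `sm`) to the pooled window level (default TRUE).
#' @return `data.table` with `chrom, start, end, context, meth, unmeth,
#'   n_sites, ml_raw, ml` (`ml` corrected when `correct = TRUE`).
#' @export
window_summarize <- function(sm, chrom_len, window_size = 3000L,
                             step = 600L, correct = TRUE) {
  r <- if (correct) attr(sm, "r") %||% 0 else 0
  dt <- data.table::as.data.table(sm)[covered == TRUE]
  K <- window_size %/% step
  out <- vector("list", 0L)
  for (cn in names(chrom_len)) {
    L <- chrom_len[[cn]]
    ws <- window_starts(L, window_size, step)
    if (nrow(ws) == 0L) next
    nb <- as.integer(ceiling(L / step))
    k0 <- (ws$start - 1L) %/% step + 1L
    k1 <- pmin(as.integer(ceiling(ws$end / step)), nb)
    chrom_sites <- dt[chrom == cn]
    for (ctx in CONTEXTS) {
      s <- chrom_sites[context == ctx]
      binm <- numeric(nb); binu <- numeric(nb); binn <- numeric(nb)
      if (nrow(s)) {
        b <- (s$pos - 1L) %/% step + 1L
        agg <- s[, .(m = sum(count_meth), u = sum(count_unmeth), n = .N),
                 by = .(bin = b)]
        binm[agg$bin] <- agg$m
        binu[agg$bin] <- agg$u
        binn[agg$bin] <- agg$n
      }
      cm <- c(0, cumsum(binm)); cu <- c(0, cumsum(binu))
      cn2 <- c(0, cumsum(binn))
      out[[length(out) + 1L]] <- data.table::data.table(
        chrom = cn, start = ws$start, end = ws$end, context = ctx,
        meth = cm[k1 + 1L] - cm[k0],
        unmeth = cu[k1 + 1L] - cu[k0],
        n_sites = as.integer(cn2[k1 + 1L] - cn2[k0]))
    }
  }
  if (length(out) == 0L)
    return(data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      context = character(), meth = numeric(), unmeth = numeric(),
      n_sites = integer(), ml_raw = numeric(), ml = numeric()))
  res <- data.table::rbindlist(out)
  res[, ml_raw := pooled_ml(meth, unmeth)]
  res[, ml := pmin(1, pmax(0, (ml_raw - r) / (1 - r)))]
  res[order(factor(chrom, levels = names(chrom_len)), start,
            factor(context, levels = CONTEXTS))]
}
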