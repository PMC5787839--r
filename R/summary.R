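#' Genome-wide methylation summary
#'
#' Computes the standard genome-wide statistics: the percentage of methylation
#' per context (methylated C sites over all covered C sites of that
#' context), the relative proportion of mCs across contexts (share of mCG,
#' mCHG and mCHH among all mC sites; sums to 100%), and per-chromosome mC
#' density tracks in fixed bins.
#'
#' @param sm_called `site_methylation` table with mC calls
#'   ([call_methylated_sites()]).
#' @param chrom_len named chromosome lengths for the density track.
#' @param bin density bin width in bp (default 10000).
#' @return object of class `global_summary`: list with `pct_methylation`
#'   (named by context, percent), `relative_mc_proportion` (named, percent,
#'   sums to 100), `density` (`data.table` chrom/start/end/context/n_mc,
#'   BED-like 0-based half-open when written), `n_covered`, `n_mc`.
#' @export
global_summary <- function(sm_called, chrom_len, bin = 10000L) {
  dt <- data.table::as.data.table(sm_called)[covered == TRUE]
  if (nrow(dt) == 0L) stop("no covered sites", call. = FALSE)
  if (!"is_mc" %in% names(dt))
    stop("run call_methylated_sites() first", call. = FALSE)
  cov_n <- dt[, .N, by = context]
  mc_n <- dt[is_mc == TRUE, .N, by = context]
  pct <- stats::setNames(rep(NA_real_, 3L), CONTEXTS)
  nmc <- stats::setNames(rep(0L, 3L), CONTEXTS)
  for (ctx in CONTEXTS) {
    nc <- cov_n[context == ctx]$N
    nm <- mc_n[context == ctx]$N
    if (length(nm) == 0L) nm <- 0L
    nmc[ctx] <- nm
    if (length(nc) == 1L && nc > 0L) pct[ctx] <- 100 * nm / nc
  }
  total_mc <- sum(nmc)
  rel <- if (total_mc > 0) 100 * nmc / total_mc
         else stats::setNames(rep(NA_real_, 3L), CONTEXTS)

  mc <- dt[is_mc == TRUE]
  density <- if (nrow(mc)) {
    d <- mc[, .(n_mc = .N),
            by = .(chrom, bin_i = (pos - 1L) %/% bin, context)]
    d[, `:=`(start = bin_i * bin + 1L,
             end = pmin((bin_i + 1L) * bin,
                        chrom_len[chrom]))]
    d[, bin_i := NULL]
    d[order(factor(chrom, levels = names(chrom_len)), start,
            factor(context, levels = CONTEXTS)),
      .(chrom, start, end, context, n_mc)]
  } else data.table::data.table(chrom = character(), start = integer(),
                                end = integer(), context = character(),
                                n_mc = integer())
  structure(list(pct_methylation = pct,
                 relative_mc_proportion = rel,
                 density = density,
                 n_covered = nrow(dt), n_mc = total_mc),
            class = "global_summary")
}

#' @export
print.global_summary <- function(x, ...) {
  cat("global_summary over", format(x$n_covered, big.mark = ","),
      "covered cytosines (", format(x$n_mc, big.mark = ","), "mC )\n")
  cat("  % methylation (mC / covered C):",
      paste(sprintf("%s %.1f%%", CONTEXTS, x$pct_methylation),
            collapse = ", "), "\n")
  cat("  relative mC proportion:",
      paste(sprintf("%s %.1f%%", CONTEXTS, x$relative_mc_proportion),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a bedGraph-like mC density track
#' @param summary a [global_summary()] object.
#' @param path output TSV (chrom, 0-based start, end, context, mC count).
#' @return `path`, invisibly.
#' @export
write_density_track <- function(summary, path) {
  d <- data.table::copy(summary$density)
  d[, start := start - 1L]
  data.table::fwrite(d, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
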