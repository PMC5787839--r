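## Per-site methylation estimation, nonconversion correction, mC calling.

#' Pool replicate cytosine reports by count summation
#'
#' @param reports list of cytosine-record `data.table`s for one condition.
#' @return single `data.table` with counts summed per
#'   (chrom, pos, strand, context, trinucleotide).
#' @export
pool_replicates <- function(reports) {
  stopifnot(is.list(reports), length(reports) >= 1L)
  dt <- data.table::rbindlist(reports)
  dt <- dt[, .(count_meth = sum(count_meth),
               count_unmeth = sum(count_unmeth)),
           by = .(chrom, pos, strand, context, trinucleotide)]
  dt[order(factor(chrom, levels = unique(chrom)), pos, strand)]
}

#' Estimate the bisulfite nonconversion rate from a spike-in
#'
#' An unmethylated spike-in genome (lambda phage DNA added before bisulfite
#' treatment) has no true methylation, so any methylated calls on it measure
#' the nonconversion rate r: the probability that an unmethylated cytosine
#' escapes conversion and reads as methylated. r is the pooled methylated
#' read fraction over all spike-in cytosines; the conversion rate is 1 - r.
#'
#' @param records cytosine records (any chromosomes; only `spike_in_chrom`
#'   rows are used).
#' @param spike_in_chrom name of the spike-in chromosome.
#' @param min_reads minimum pooled read count required for a stable
#'   estimate (default 1e4).
#' @return list with `r`, `conversion_rate` (= 1 - r), `n_reads`, `n_sites`.
#' @export
estimate_nonconversion <- function(records, spike_in_chrom,
                                   min_reads = 1e4) {
  sub <- data.table::as.data.table(records)[chrom == spike_in_chrom]
  n_reads <- sum(sub$count_meth) + sum(sub$count_unmeth)
  if (nrow(sub) == 0L || n_reads < min_reads)
    stop("insufficient spike-in coverage on '", spike_in_chrom, "' (",
         n_reads, " reads < ", min_reads,
         "); supply the nonconversion rate directly via the r override",
         call. = FALSE)
  r <- sum(sub$count_meth) / n_reads
  list(r = r, conversion_rate = 1 - r,
       n_reads = n_reads, n_sites = nrow(sub))
}

#' Per-site methylation levels with nonconversion correction
#'
#' The raw methylation level of a cytosine is
#' ML = count_meth / (count_meth + count_unmeth). Given a nonconversion rate
#' r, the corrected level is (ML - r) / (1 - r), clamped to \[0, 1\]
#' (sampling noise at unmethylated sites can push the corrected value
#' below zero).
#'
#' @param records cytosine records (see [read_cytosine_report()]).
#' @param r nonconversion rate in \[0, 1).
#' @param min_coverage minimum total read count for a site to be flagged
#'   `covered` (default 4).
#' @return `data.table` of class `site_methylation` with the record columns
#'   plus `coverage`, `ml_raw`, `ml_corrected`, `covered`; the value of `r`
#'   and `min_coverage` are kept as attributes.
#' @export
compute_site_methylation <- function(records, r, min_coverage = 4L) {
  check_prob(r, "r")
  if (r >= 1) stop("r must be < 1", call. = FALSE)
  dt <- data.table::copy(data.table::as.data.table(records))
  dt[, coverage := count_meth + count_unmeth]
  dt[, ml_raw := ifelse(coverage > 0L, count_meth / coverage, NA_real_)]
  dt[, ml_corrected := pmin(1, pmax(0, (ml_raw - r) / (1 - r)))]
  dt[, covered := coverage >= min_coverage]
  data.table::setattr(dt, "r", r)
  data.table::setattr(dt, "min_coverage", as.integer(min_coverage))
  dt[]
}

#' Call methylated cytosines against the nonconversion background
#'
#' The percentage-of-methylation summary (fraction of C sites that are
#' methylated) needs a binary per-site call. Each covered site's methylated
#' read count is tested one-sided against a Binomial(coverage, r) null --
#' the chance of observing that many methylated reads from nonconversion
#' alone -- and p-values are Benjamini-Hochberg adjusted across all covered
#' sites; a site is called mC when q < `fdr_alpha`.
#'
#' @param sm a `site_methylation` table from [compute_site_methylation()].
#' @param r nonconversion rate; defaults to the value stored on `sm`.
#' @param fdr_alpha FDR threshold (default 0.05).
#' @return `sm` with added columns `p_mc`, `q_mc`, `is_mc` (NA for
#'   uncovered sites).
#' @export
call_methylated_sites <- function(sm, r = attr(sm, "r"), fdr_alpha = 0.05) {
  check_prob(r, "r")
  dt <- data.table::copy(sm)
  dt[, `:=`(p_mc = NA_real_, q_mc = NA_real_, is_mc = NA)]
  idx <- which(dt$covered)
  if (length(idx)) {
    m <- dt$count_meth[idx]
    n <- dt$coverage[idx]
    ## one-sided upper tail: P(X >= m) under X ~ Binom(n, r).
    ## With r = 0 any methylated read is impossible under the null (p = 0).
    p <- ifelse(m == 0L, 1,
                stats::pbinom(m - 1L, n, r, lower.tail = FALSE))
    q <- stats::p.adjust(p, method = "BH")
    dt[idx, `:=`(p_mc = p, q_mc = q, is_mc = q < fdr_alpha)]
  }
  data.table::setattr(dt, "r", attr(sm, "r"))
  data.table::setattr(dt, "min_coverage", attr(sm, "min_coverage"))
  dt[]
}

#' Merge symmetric CpG strand pairs
#'
#' CG methylation is symmetric: the plus-strand cytosine at position p and
#' the minus-strand cytosine at p+1 interrogate the same CpG dyad. This
#' optional operation pools the read counts of such pairs into one record
#' (reported at the plus-strand position). Unpaired CG sites are passed
#' through with `paired = FALSE`. Strands are otherwise always reported
#' separately by the rest of the pipeline.
#'
#' @param sm `site_methylation` table; only CG rows are used.
#' @return `data.table` of merged CG sites with recomputed levels and a
#'   `paired` flag.
#' @export
merge_symmetric_cpg <- function(sm) {
  r <- attr(sm, "r") %||% 0
  min_cov <- attr(sm, "min_coverage") %||% 4L
  cg <- data.table::as.data.table(sm)[context == "CG"]
  plus <- cg[strand == "+"]
  minus <- cg[strand == "-"]
  minus_key <- minus[, .(chrom, pos = pos - 1L,
                         m2 = count_meth, u2 = count_unmeth)]
  merged <- merge(plus[, .(chrom, pos, count_meth, count_unmeth)],
                  minus_key, by = c("chrom", "pos"), all = TRUE)
  merged[, paired := !is.na(count_meth) & !is.na(m2)]
  merged[is.na(count_meth), `:=`(count_meth = 0L, count_unmeth = 0L)]
  merged[is.na(m2), `:=`(m2 = 0L, u2 = 0L)]
  merged[, `:=`(count_meth = count_meth + m2,
                count_unmeth = count_unmeth + u2)]
  merged[, `:=`(m2 = NULL, u2 = NULL)]
  merged[, `:=`(strand = "+", context = "CG")]
  out <- compute_site_methylation(
    merged[, .(chrom, pos, strand, context,
               trinucleotide = NA_character_, count_meth, count_unmeth)],
    r = r, min_coverage = min_cov)
  out[, paired := merged$paired]
  out[order(factor(chrom, levels = unique(chrom)), pos)]
}
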