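## Quintile stratifications and per-gene region methylation.

#' Partition items into quintiles with an optional special class
#'
#' Items flagged `special` are extracted first (e.g. nonexpressed genes
#' with FPKM < 0.1, or genes whose region carries no called methylation);
#' the remainder is rank-ordered ascending and split into five groups,
#' 1st = lowest to 5th = highest. Group sizes differ by at most one, with
#' the larger groups at the low end; ties are broken by the stable order of
#' item ids.
#'
#' @param values numeric vector.
#' @param ids item identifiers (same length).
#' @param special optional logical vector marking special-class items.
#' @param special_label label for the special class (default `"none"`).
#' @return `data.table` with `id`, `value`, `group` (`special_label`,
#'   `"1st"` ... `"5th"`).
#' @export
quintile_partition <- function(values, ids, special = NULL,
                               special_label = "none") {
  stopifnot(length(values) == length(ids))
  if (anyDuplicated(ids)) stop("duplicate item ids", call. = FALSE)
  if (is.null(special)) special <- rep(FALSE, length(values))
  dt <- data.table::data.table(id = as.character(ids), value = values,
                               special = special)
  spec <- dt[special == TRUE][, group := special_label]
  rest <- dt[special == FALSE]
  n <- nrow(rest)
  if (n < 5L)
    stop("need at least 5 items outside the special class, got ", n,
         call. = FALSE)
  rest <- rest[order(value, id)]
  base <- n %/% 5L
  rem <- n %% 5L
  sizes <- rep(base, 5L) + c(rep(1L, rem), rep(0L, 5L - rem))
  labels <- c("1st", "2nd", "3rd", "4th", "5th")
  rest[, group := rep(labels, sizes)]
  out <- rbind(spec[, .(id, value, group)], rest[, .(id, value, group)])
  out[order(id)]
}

#' Per-gene region methylation
#'
#' Count-pooled methylation of each gene's promoter, body or TTR over
#' covered cytosines, plus the number of covered sites and of FDR-called
#' mC sites in the region (used to classify genes as methylated or
#' unmethylated).
#'
#' @param sm `site_methylation` table with mC calls
#'   ([call_methylated_sites()]).
#' @param genes a [gene_models()] object.
#' @param region `"promoter"`, `"body"` or `"TTR"`.
#' @param span flank width for promoter/TTR (default 2000).
#' @param contexts contexts pooled into the level (default all three).
#' @return `data.table` with `gene_id`, `ml`, `n_sites`, `n_mc`.
#' @export
gene_region_methylation <- function(sm, genes,
                                    region = c("promoter", "body", "TTR"),
                                    span = 2000L, contexts = CONTEXTS) {
  region <- match.arg(region)
  has_calls <- "is_mc" %in% names(sm)
  reg <- gene_region_table(genes, span, span)
  reg <- reg[reg$region == region]
  dt <- data.table::as.data.table(sm)[covered == TRUE &
                                        context %in% contexts]
  hit <- GenomicRanges::findOverlaps(site_ranges(dt), ranges_of(reg))
  dd <- data.table::data.table(
    gene_id = reg$gene_id[S4Vectors::subjectHits(hit)],
    m = dt$count_meth[S4Vectors::queryHits(hit)],
    u = dt$count_unmeth[S4Vectors::queryHits(hit)],
    mc = if (has_calls) dt$is_mc[S4Vectors::queryHits(hit)] else NA)
  agg <- dd[, .(ml = pooled_ml(sum(m), sum(u)), n_sites = .N,
                n_mc = if (has_calls) sum(mc, na.rm = TRUE) else NA_integer_),
            by = gene_id]
  out <- merge(data.table::data.table(gene_id = genes$genes$gene_id),
               agg, by = "gene_id", all.x = TRUE)
  out[is.na(n_sites), `:=`(n_sites = 0L,
                           n_mc = if (has_calls) 0L else NA_integer_)]
  out[order(gene_id)]
}

#' Expression distributions across methylation-level groups
#'
#' Genes are grouped by the methylation of one region into `unmethylated`
#' (fewer than `min_sites` covered cytosines or no FDR-called mC site in
#' the region) plus five quintiles of region methylation among methylated
#' genes; per group the distribution of log10(FPKM + 0.01) is summarized
#' with quartile/whisker boxplot statistics. Genes whose region has no
#' covered cytosine at all are excluded and counted in `n_excluded`.
#'
#' @param expression table with `gene_id` and `fpkm`.
#' @param region_ml per-gene region methylation from
#'   [gene_region_methylation()].
#' @param min_sites minimum covered cytosines for a region to be
#'   classifiable as methylated (default 5).
#' @return list with `groups` (`data.table` gene_id/group), `summary`
#'   (per-group boxplot statistics of log10 FPKM), `n_excluded`.
#' @export
expression_by_methylation_group <- function(expression, region_ml,
                                            min_sites = 5L) {
  expr <- data.table::as.data.table(expression)
  if (!"fpkm" %in% names(expr) && "fpkm_control" %in% names(expr))
    expr[, fpkm := fpkm_control]
  dt <- merge(data.table::as.data.table(region_ml),
              expr[, .(gene_id, fpkm)], by = "gene_id")
  excluded <- dt[n_sites == 0L]
  dt <- dt[n_sites > 0L]
  unmeth <- dt$n_sites < min_sites | dt$n_mc == 0L
  qa <- quintile_partition(dt$ml, dt$gene_id, special = unmeth,
                           special_label = "unmethylated")
  groups <- merge(qa[, .(gene_id = id, group)], dt[, .(gene_id, fpkm)],
                  by = "gene_id")
  lv <- c("unmethylated", "1st", "2nd", "3rd", "4th", "5th")
  summ <- groups[, {
    bs <- boxplot_stats(log10(fpkm + 0.01))
    data.table::as.data.table(bs)
  }, by = group]
  summ <- summ[order(factor(group, levels = lv))]
  list(groups = groups[, .(gene_id, group)], summary = summ[],
       n_excluded = nrow(excluded))
}
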