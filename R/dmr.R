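## Differentially methylated regions, genes and transposable elements.

#' Call differentially methylated regions between two conditions
#'
#' Replicates are pooled by count summation per condition beforehand (see
#' [pool_replicates()]). Per context, read counts of covered sites are
#' summed in sliding windows (1000 bp window, 100 bp step) for each
#' condition; every window with at least `min_sites` covered cytosines of
#' that context in both conditions is tested with a two-sided Fisher exact
#' test on the pooled 2x2 count table, and p-values are BH-adjusted per
#' context across all tested windows genome-wide. Significant windows
#' (q < `q_alpha` and |case ML - control ML| >= `min_delta`) of the same
#' context and direction are merged when overlapping or book-ended, and the
#' merged DMR's statistics are recomputed from the site counts on the
#' merged span.
#'
#' @param case_sm,control_sm `site_methylation` tables for treatment and
#'   control (replicates already pooled).
#' @param chrom_len named chromosome lengths.
#' @param window_size,step sliding-window geometry in bp (defaults 1000/100).
#' @param q_alpha FDR threshold on window tests (default 0.05).
#' @param min_delta minimum absolute pooled methylation difference for a
#'   window to count as significant (default 0.1).
#' @param min_sites minimum covered cytosines of the context per condition
#'   in a window (default 5).
#' @param contexts contexts to test (default CG, CHG, CHH).
#' @return object of class `dmr_result`: list with `dmrs` (`data.table`
#'   chrom/start/end/context/status/ml_case/ml_control/delta_ml/p_min/
#'   q_min/n_windows) and `windows` (all tested windows with counts, `p`,
#'   `q`, `delta_ml`, `significant`).
#' @export
call_dmrs <- function(case_sm, control_sm, chrom_len,
                      window_size = 1000L, step = 100L,
                      q_alpha = 0.05, min_delta = 0.1, min_sites = 5L,
                      contexts = CONTEXTS) {
  w_case <- window_summarize(case_sm, chrom_len, window_size, step,
                             correct = FALSE)
  w_ctrl <- window_summarize(control_sm, chrom_len, window_size, step,
                             correct = FALSE)
  key <- c("chrom", "start", "end", "context")
  wt <- merge(w_case[, c(key, "meth", "unmeth", "n_sites"), with = FALSE],
              w_ctrl[, c(key, "meth", "unmeth", "n_sites"), with = FALSE],
              by = key, all = TRUE, suffixes = c("_case", "_control"))
  for (cc in grep("^(meth|unmeth|n_sites)_", names(wt), value = TRUE))
    wt[is.na(get(cc)), (cc) := 0]
  wt <- wt[context %in% contexts]
  wt[, tested := n_sites_case >= min_sites & n_sites_control >= min_sites]
  wt <- wt[tested == TRUE]
  if (nrow(wt) == 0L) {
    warning("no windows satisfied the minimum-site requirement",
            call. = FALSE)
    empty <- data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      context = character(), status = character(), ml_case = numeric(),
      ml_control = numeric(), delta_ml = numeric(), p_min = numeric(),
      q_min = numeric(), n_windows = integer())
    return(structure(list(dmrs = empty, windows = wt),
                     class = "dmr_result"))
  }
  wt[, p := fisher_exact_two_sided(meth_case, unmeth_case,
                                   meth_control, unmeth_control)]
  wt[, q := benjamini_hochberg(p), by = context]
  wt[, ml_case := pooled_ml(meth_case, unmeth_case)]
  wt[, ml_control := pooled_ml(meth_control, unmeth_control)]
  wt[, delta_ml := ml_case - ml_control]
  wt[, significant := q < q_alpha & abs(delta_ml) >= min_delta &
       !is.na(delta_ml)]

  sig <- wt[significant == TRUE]
  dmrs <- if (nrow(sig)) {
    sig[, direction := ifelse(delta_ml > 0, "hyper", "hypo")]
    merged <- sig[, {
      gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
      red <- GenomicRanges::reduce(gr, min.gapwidth = 1L)
      hit <- GenomicRanges::findOverlaps(gr, red)
      grp <- S4Vectors::subjectHits(hit)[order(S4Vectors::queryHits(hit))]
      .SD[, .(start = min(start), end = max(end),
              p_min = min(p), q_min = min(q), n_windows = .N),
          by = .(grp = grp)][, grp := NULL]
    }, by = .(chrom, context, direction)]
    ## recompute pooled levels on the merged span from the site tables
    recompute <- function(sm, spans) {
      s <- data.table::as.data.table(sm)[covered == TRUE]
      gr_sites <- site_ranges(s)
      gr_spans <- ranges_of(spans)
      hit <- GenomicRanges::findOverlaps(gr_sites, gr_spans)
      dd <- data.table::data.table(
        span = S4Vectors::subjectHits(hit),
        ctx = s$context[S4Vectors::queryHits(hit)],
        m = s$count_meth[S4Vectors::queryHits(hit)],
        u = s$count_unmeth[S4Vectors::queryHits(hit)])
      dd <- dd[ctx == spans$context[span]]
      agg <- dd[, .(m = sum(m), u = sum(u)), by = span]
      ml <- rep(NA_real_, nrow(spans))
      ml[agg$span] <- pooled_ml(agg$m, agg$u)
      ml
    }
    merged[, ml_case := recompute(case_sm, merged)]
    merged[, ml_control := recompute(control_sm, merged)]
    merged[, delta_ml := ml_case - ml_control]
    merged[, status := ifelse(delta_ml >= 0, "hyper", "hypo")]
    ## keep the window-level direction when the recomputed span is flat
    merged[delta_ml == 0, status := direction]
    merged[order(factor(chrom, levels = names(chrom_len)), start,
                 factor(context, levels = CONTEXTS)),
           .(chrom, start, end, context, status, ml_case, ml_control,
             delta_ml, p_min, q_min, n_windows)]
  } else {
    data.table::data.table(
      chrom = character(), start = integer(), end = integer(),
      context = character(), status = character(), ml_case = numeric(),
      ml_control = numeric(), delta_ml = numeric(), p_min = numeric(),
      q_min = numeric(), n_windows = integer())
  }
  structure(list(dmrs = dmrs, windows = wt[]), class = "dmr_result")
}

#' @export
print.dmr_result <- function(x, ...) {
  cat("dmr_result:", nrow(x$dmrs), "DMRs from", nrow(x$windows),
      "tested windows\n")
  if (nrow(x$dmrs))
    print(x$dmrs[, .N, by = .(context, status)])
  invisible(x)
}

#' Assign DMRs to gene regions
#'
#' A gene is hyper-/hypomethylated in a region when at least one DMR of
#' that status overlaps the region by >= 1 bp. Regions are the promoter
#' (`promoter_span` bp upstream of the transcript start, strand-aware), the
#' gene body (transcript span), and the transcriptional termination region
#' (TTR; `ttr_span` bp downstream of the transcript end). A gene may be
#' both hyper- and hypomethylated through different regions or contexts;
#' each combination is reported as its own row.
#'
#' @param dmrs DMR table (from `call_dmrs()$dmrs`).
#' @param genes a [gene_models()] object.
#' @param promoter_span,ttr_span flank sizes in bp (defaults 2000).
#' @return `data.table` with `feature_id`, `region`
#'   (promoter/body/TTR), `context`, `status`, `n_dmrs`.
#' @export
assign_dmr_features <- function(dmrs, genes, promoter_span = 2000L,
                                ttr_span = 2000L) {
  stopifnot(inherits(genes, "gene_models"))
  dmrs <- data.table::as.data.table(dmrs)
  if (nrow(dmrs) == 0L)
    return(data.table::data.table(feature_id = character(),
                                  region = character(), context = character(),
                                  status = character(), n_dmrs = integer()))
  reg <- gene_region_table(genes, promoter_span, ttr_span)
  hit <- GenomicRanges::findOverlaps(ranges_of(dmrs), ranges_of(reg))
  out <- data.table::data.table(
    feature_id = reg$gene_id[S4Vectors::subjectHits(hit)],
    region = reg$region[S4Vectors::subjectHits(hit)],
    context = dmrs$context[S4Vectors::queryHits(hit)],
    status = dmrs$status[S4Vectors::queryHits(hit)])
  out <- out[, .(n_dmrs = .N), by = .(feature_id, region, context, status)]
  data.table::setorder(out, feature_id, region, context, status)
  out[]
}

## promoter/body/TTR intervals per gene, strand-aware, clipped at 1.
gene_region_table <- function(genes, promoter_span = 2000L,
                              ttr_span = 2000L) {
  g <- genes$genes
  plus <- g$strand == "+"
  prom <- data.table::data.table(
    gene_id = g$gene_id, chrom = g$chrom, region = "promoter",
    start = ifelse(plus, pmax(1L, g$start - promoter_span), g$end + 1L),
    end = ifelse(plus, g$start - 1L, g$end + promoter_span))
  body <- data.table::data.table(
    gene_id = g$gene_id, chrom = g$chrom, region = "body",
    start = g$start, end = g$end)
  ttr <- data.table::data.table(
    gene_id = g$gene_id, chrom = g$chrom, region = "TTR",
    start = ifelse(plus, g$end + 1L, pmax(1L, g$start - ttr_span)),
    end = ifelse(plus, g$end + ttr_span, g$start - 1L))
  out <- rbind(prom, body, ttr)
  out[end >= start]
}

#' Test transposable elements for differential methylation
#'
#' For each TE, covered-site read counts are pooled per context (plus a
#' `combined` test over all contexts, the "total mC sites" variant) and
#' compared between conditions with a two-sided Fisher exact test; p-values
#' are BH-adjusted across TEs within each context. A TE is called
#' differentially methylated when q < `alpha` (or raw p < `alpha` when
#' `use_fdr = FALSE`) and its methylation fold change exceeds
#' `fold_threshold`. The fold change is
#' (ML_case + pseudocount) / (ML_control + pseudocount), inverted if below
#' one, so it is always >= 1 and finite at zero methylation.
#'
#' @param tes a [te_annotation()] table.
#' @param case_sm,control_sm pooled `site_methylation` tables.
#' @param contexts contexts to test; `"combined"` pools all contexts.
#' @param min_sites minimum covered cytosines per condition within the TE
#'   (default 5); TEs below it are skipped.
#' @param pseudocount added to both levels before the ratio (default 0.01).
#' @param alpha significance threshold (default 0.05).
#' @param fold_threshold minimum fold change (default 2).
#' @param use_fdr apply the threshold to BH-adjusted q (default TRUE)
#'   rather than raw p.
#' @return `data.table` with `feature_id`, `te_class`, `context`,
#'   `ml_case`, `ml_control`, `fold_change`, `status` (hyper/hypo), `p`,
#'   `q`, `differential`; skipped TEs are absent.
#' @export
test_te_differential <- function(tes, case_sm, control_sm,
                                 contexts = c(CONTEXTS, "combined"),
                                 min_sites = 5L, pseudocount = 0.01,
                                 alpha = 0.05, fold_threshold = 2,
                                 use_fdr = TRUE) {
  te_counts <- function(sm) {
    s <- data.table::as.data.table(sm)[covered == TRUE]
    hit <- GenomicRanges::findOverlaps(site_ranges(s), ranges_of(tes))
    dd <- data.table::data.table(
      te = S4Vectors::subjectHits(hit),
      context = s$context[S4Vectors::queryHits(hit)],
      m = s$count_meth[S4Vectors::queryHits(hit)],
      u = s$count_unmeth[S4Vectors::queryHits(hit)])
    per_ctx <- dd[, .(m = sum(m), u = sum(u), n = .N), by = .(te, context)]
    comb <- dd[, .(m = sum(m), u = sum(u), n = .N,
                   context = "combined"), by = te]
    rbind(per_ctx, comb[, .(te, context, m, u, n)])
  }
  cc <- te_counts(case_sm)
  kk <- te_counts(control_sm)
  tab <- merge(cc, kk, by = c("te", "context"), suffixes = c("_case", "_ctrl"))
  tab <- tab[context %in% contexts &
               n_case >= min_sites & n_ctrl >= min_sites]
  if (nrow(tab) == 0L) {
    message("no TE passed the coverage requirement")
    return(data.table::data.table(
      feature_id = character(), te_class = character(),
      context = character(), ml_case = numeric(), ml_control = numeric(),
      fold_change = numeric(), status = character(), p = numeric(),
      q = numeric(), differential = logical()))
  }
  tab[, p := fisher_exact_two_sided(m_case, u_case, m_ctrl, u_ctrl)]
  tab[, q := benjamini_hochberg(p), by = context]
  tab[, ml_case := pooled_ml(m_case, u_case)]
  tab[, ml_control := pooled_ml(m_ctrl, u_ctrl)]
  ratio <- (tab$ml_case + pseudocount) / (tab$ml_control + pseudocount)
  tab[, fold_change := pmax(ratio, 1 / ratio)]
  tab[, status := ifelse(ml_case >= ml_control, "hyper", "hypo")]
  crit <- if (use_fdr) tab$q else tab$p
  tab[, differential := crit < alpha & fold_change > fold_threshold]
  out <- tab[, .(feature_id = tes$te_id[te], te_class = tes$te_class[te],
                 context, ml_case, ml_control, fold_change, status, p, q,
                 differential)]
  data.table::setorder(out, feature_id, context)
  out[]
}
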