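## Integration of differential methylation with gene expression.

#' Overlap of differentially methylated and differentially expressed genes
#'
#' Counts genes that are hypermethylated and down-regulated, hypomethylated
#' and up-regulated, and the two concordant-direction combinations. A gene
#' hyper- and hypomethylated through different regions or contexts is
#' counted in both methylation sets. Hypergeometric enrichment p-values
#' (over-representation of each DEG set within each DMG set, relative to
#' the expression-table universe) are included.
#'
#' @param dmfeatures `data.table` from [assign_dmr_features()] (columns
#'   `feature_id`, `status`).
#' @param expression table with `gene_id` and `de_label` (up/down/none).
#' @return list with `counts` (named: hyper_down, hypo_up, hyper_up,
#'   hypo_down), `genes` (list of gene-id vectors), `enrichment_p`
#'   (named: hyper_down, hypo_up), `universe_size`.
#' @export
overlap_dmg_deg <- function(dmfeatures, expression) {
  dmf <- data.table::as.data.table(dmfeatures)
  expr <- data.table::as.data.table(expression)
  if (!"de_label" %in% names(expr))
    stop("expression table needs a de_label column", call. = FALSE)
  if (anyDuplicated(expr$gene_id)) {
    warning("duplicate gene ids in expression table; deduplicated",
            call. = FALSE)
    expr <- unique(expr, by = "gene_id")
  }
  if (nrow(dmf)) {
    match_rate <- mean(unique(dmf$feature_id) %in% expr$gene_id)
    if (match_rate < 0.5)
      stop("fewer than half of the differentially methylated gene ids ",
           "match the expression table; check that both use the same ",
           "annotation", call. = FALSE)
  }
  hyper <- unique(dmf[status == "hyper"]$feature_id)
  hypo <- unique(dmf[status == "hypo"]$feature_id)
  up <- expr[de_label == "up"]$gene_id
  down <- expr[de_label == "down"]$gene_id
  genes <- list(
    hyper_down = intersect(hyper, down),
    hypo_up = intersect(hypo, up),
    hyper_up = intersect(hyper, up),
    hypo_down = intersect(hypo, down))
  counts <- vapply(genes, length, integer(1))
  universe <- expr$gene_id
  enrich <- function(set_a, set_b) {
    a <- intersect(set_a, universe); b <- intersect(set_b, universe)
    k <- length(intersect(a, b))
    ## P(X >= k) for X ~ Hypergeom drawing |a| from universe with |b| marked
    stats::phyper(k - 1, length(b), length(universe) - length(b),
                  length(a), lower.tail = FALSE)
  }
  list(counts = counts, genes = genes,
       enrichment_p = c(hyper_down = enrich(hyper, down),
                        hypo_up = enrich(hypo, up)),
       universe_size = length(universe))
}

#' Counts for every region of a Venn diagram
#'
#' @param sets named list (>= 2) of vectors; duplicates within a set are
#'   ignored.
#' @return `data.table` with `region` (e.g. `"A&B"`) and `count` of
#'   elements exclusive to that membership pattern; counts sum to the size
#'   of the union.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2L) stop("need at least 2 sets", call. = FALSE)
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named", call. = FALSE)
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  nm <- names(sets)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1L, ,
                                                                   drop = FALSE]
  names(patterns) <- nm
  counts <- apply(patterns, 1L, function(pt) {
    if (length(universe) == 0L) return(0L)
    sum(apply(member, 1L, function(row) all(row == pt)))
  })
  region <- apply(patterns, 1L, function(pt) paste(nm[as.logical(pt)],
                                                   collapse = "&"))
  data.table::data.table(region = region, count = as.integer(counts))
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact (full enumeration of the rank-sum distribution) when both samples
#' are tie-free and the smaller has at most 8 observations; otherwise the
#' normal approximation with tie and continuity corrections.
#'
#' @param x,y numeric samples (non-empty).
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && min(length(x), length(y)) <= 8L
  res <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  unname(res$p.value)
}

#' Expression-change comparison of methylation groups
#'
#' Summarizes per-gene expression changes (e.g. log2 fold changes) for all
#' genes and for hyper-/hypomethylated genes as boxplot statistics
#' (quartiles by linear interpolation; whiskers at the most extreme points
#' within 1.5 interquartile ranges of the quartiles), with a two-sided
#' Wilcoxon rank-sum p-value of each methylation group against all genes.
#'
#' @param all_values expression changes of all genes.
#' @param hyper_values,hypo_values expression changes of the hyper- and
#'   hypomethylated gene sets.
#' @return `data.table` with group, n, quartiles, whiskers, `wilcoxon_p`
#'   (NA for the reference group) and a `reliable` flag (FALSE when the
#'   group has fewer than 3 values).
#' @export
group_expression_comparison <- function(all_values, hyper_values,
                                        hypo_values) {
  one <- function(label, v, ref = NULL) {
    bs <- boxplot_stats(v)
    p <- if (is.null(ref) || length(v) == 0L) NA_real_
         else wilcoxon_rank_sum(v, ref)
    data.table::data.table(
      group = label, n = bs$n, q1 = bs$q1, median = bs$median, q3 = bs$q3,
      whisker_lo = bs$whisker_lo, whisker_hi = bs$whisker_hi,
      wilcoxon_p = p, reliable = bs$n >= 3L)
  }
  rbind(one("all", all_values),
        one("hyper", hyper_values, all_values),
        one("hypo", hypo_values, all_values))
}

#' Relative expression by the comparative Ct method
#'
#' Computes 2^-ddCt where
#' ddCt = (Ct_target,treated - Ct_reference,treated) -
#' (Ct_target,control - Ct_reference,control); the reference gene is an
#' endogenous control (e.g. elongation factor 1 alpha) and the untreated
#' sample is the calibrator.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   positive qPCR cycle-threshold values.
#' @return relative expression fold change (1 = unchanged).
#' @export
relative_expression_ddct <- function(ct_target_treated, ct_ref_treated,
                                     ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated,
           ct_target_control, ct_ref_control)
  if (any(!is.finite(cts)) || any(cts <= 0))
    stop("Ct values must be positive", call. = FALSE)
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}

#' Per-gene methylation/expression integration table
#'
#' One row per annotated gene: methylation status per region (hyper, hypo,
#' both or none, collapsed over contexts), overall status, the DE label,
#' and the log2 expression change
#' log2((FPKM_case + 0.01) / (FPKM_control + 0.01)) when both condition
#' FPKMs are present.
#'
#' @param dmfeatures `data.table` from [assign_dmr_features()].
#' @param expression table with `gene_id`, `de_label` and either `fpkm` or
#'   `fpkm_control`/`fpkm_case`.
#' @param genes a [gene_models()] object (defines the gene universe).
#' @return `data.table` with `gene_id`, `status_promoter`, `status_body`,
#'   `status_TTR`, `status_any`, `de_label`, `log2fc`.
#' @export
build_integration_table <- function(dmfeatures, expression, genes) {
  expr <- data.table::as.data.table(expression)
  dmf <- data.table::as.data.table(dmfeatures)
  out <- data.table::data.table(gene_id = genes$genes$gene_id)
  collapse <- function(st) {
    if (length(st) == 0L) return("none")
    has_hyper <- "hyper" %in% st; has_hypo <- "hypo" %in% st
    if (has_hyper && has_hypo) "both"
    else if (has_hyper) "hyper" else "hypo"
  }
  for (reg in c("promoter", "body", "TTR")) {
    sub <- dmf[region == reg, .(st = collapse(status)), by = feature_id]
    col <- paste0("status_", reg)
    out[, (col) := "none"]
    if (nrow(sub))
      out[sub, (col) := i.st, on = c(gene_id = "feature_id")]
  }
  any_st <- dmf[, .(st = collapse(status)), by = feature_id]
  out[, status_any := "none"]
  if (nrow(any_st))
    out[any_st, status_any := i.st, on = c(gene_id = "feature_id")]
  if ("de_label" %in% names(expr))
    out <- merge(out, expr[, .(gene_id, de_label)], by = "gene_id",
                 all.x = TRUE)
  if (all(c("fpkm_control", "fpkm_case") %in% names(expr))) {
    out <- merge(out, expr[, .(gene_id,
                               log2fc = log2((fpkm_case + 0.01) /
                                               (fpkm_control + 0.01)))],
                 by = "gene_id", all.x = TRUE)
  }
  out[order(gene_id)]
}
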