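## Dense CG site table over one chromosome with a given level per region.
make_sites <- function(L, ml_fun, cov = 20L, spacing = 10L) {
  pos <- seq(5L, L - 5L, by = spacing)
  m <- as.integer(round(cov * ml_fun(pos)))
  data.table::data.table(
    chrom = "chr1", pos = pos, strand = "+",
    count_meth = m, count_unmeth = cov - m,
    context = "CG", trinucleotide = "CGA")
}

test_that("identical conditions yield no DMRs", {
  rec <- make_sites(5000L, function(p) 0.3)
  sm <- compute_site_methylation(rec, r = 0)
  res <- call_dmrs(sm, sm, c(chr1 = 5000L))
  expect_equal(nrow(res$dmrs), 0L)
  expect_true(all(res$windows$p == 1))
})

test_that("overlapping same-direction significant windows merge into one DMR", {
  base <- function(p) 0.1
  elevated <- function(p) ifelse(p >= 1001 & p <= 2100, 0.7, 0.1)
  ctrl <- compute_site_methylation(make_sites(6000L, base), r = 0)
  case <- compute_site_methylation(make_sites(6000L, elevated), r = 0)
  res <- call_dmrs(case, ctrl, c(chr1 = 6000L))
  expect_equal(nrow(res$dmrs), 1L)
  d <- res$dmrs
  expect_equal(d$status, "hyper")
  expect_equal(d$context, "CG")
  ## merged span covers the differential region (window resolution 100 bp)
  expect_lte(d$start, 1001L)
  expect_gte(d$end, 2100L)
  expect_gt(d$n_windows, 1L)
  expect_true(d$ml_case > d$ml_control)
})

test_that("planted DMRs are recovered with correct direction on simulation", {
  sim <- small_sim()
  called <- small_called()
  res <- call_dmrs(called$case, called$control,
                   sim$config$chrom_lengths)
  expect_equal(planted_recall(res$dmrs, sim$planted), 1)
  ## merging never produces overlapping same-context same-direction DMRs
  d <- res$dmrs
  for (ctx in unique(d$context)) for (stt in unique(d$status)) {
    sub <- d[context == ctx & status == stt]
    if (nrow(sub) > 1L) {
      gr <- GenomicRanges::GRanges(sub$chrom,
                                   IRanges::IRanges(sub$start, sub$end))
      expect_equal(sum(IRanges::width(GenomicRanges::reduce(gr))),
                   sum(IRanges::width(gr)))
    }
  }
})

test_that("DMR-to-gene assignment is per region with >= 1 bp overlap", {
  genes <- gene_models(
    data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
               start = 5001L, end = 8000L),
    data.frame(gene_id = "g1", type = "exon", start = 5001L, end = 8000L))
  dmr_in_prom <- data.table::data.table(
    chrom = "chr1", start = 3500L, end = 4200L, context = "CG",
    status = "hyper")
  a1 <- assign_dmr_features(dmr_in_prom, genes)
  expect_equal(a1$region, "promoter")
  expect_equal(a1$feature_id, "g1")

  dmr_spanning <- data.table::data.table(
    chrom = "chr1", start = 4800L, end = 5300L, context = "CG",
    status = "hypo")
  a2 <- assign_dmr_features(dmr_spanning, genes)
  expect_setequal(a2$region, c("promoter", "body"))

  dmr_far <- data.table::data.table(
    chrom = "chr1", start = 20000L, end = 21000L, context = "CG",
    status = "hyper")
  expect_equal(nrow(assign_dmr_features(dmr_far, genes)), 0L)
})

test_that("TE differential test applies the fold and significance criteria", {
  tes <- te_annotation(data.frame(
    te_id = c("t1", "t2", "t3"), chrom = "chr1", strand = "+",
    start = c(1000L, 3000L, 5000L), end = c(1990L, 3990L, 5990L),
    te_class = "LTR_Gypsy"))
  lvl <- function(p) ifelse(p < 2000, 0.4, ifelse(p < 4000, 0.2, 0.5))
  ctrl_lvl <- function(p) ifelse(p < 2000, 0.1, ifelse(p < 4000, 0.2, 0))
  case <- compute_site_methylation(make_sites(7000L, lvl, cov = 50L), r = 0)
  ctrl <- compute_site_methylation(make_sites(7000L, ctrl_lvl, cov = 50L),
                                   r = 0)
  res <- test_te_differential(tes, case, ctrl, contexts = "CG")
  t1 <- res[feature_id == "t1"]
  expect_equal(t1$fold_change, 0.41 / 0.11, tolerance = 1e-12)
  expect_true(t1$differential)
  expect_equal(t1$status, "hyper")
  ## equal levels: fold 1, not differential
  t2 <- res[feature_id == "t2"]
  expect_equal(t2$fold_change, 1)
  expect_false(t2$differential)
  ## zero control methylation stays finite through the pseudocount
  t3 <- res[feature_id == "t3"]
  expect_equal(t3$fold_change, 0.51 / 0.01, tolerance = 1e-12)
})
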