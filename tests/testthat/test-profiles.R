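## A small hand-built annotation on a random 20-kb chromosome.
toy_annotation <- function(seed = 2L) {
  set.seed(seed)
  seqs <- paste(sample(c("A", "C", "G", "T"), 20000L, replace = TRUE),
                collapse = "")
  genome <- genome_sequence(c(chr1 = seqs))
  genes <- gene_models(
    data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
               strand = c("+", "-"),
               start = c(3001L, 12001L), end = c(5000L, 14000L)),
    rbind(
      data.frame(gene_id = "g1", type = c("exon", "utr5", "cds", "utr3"),
                 start = c(3001L, 3001L, 3201L, 4801L),
                 end = c(5000L, 3200L, 4800L, 5000L)),
      data.frame(gene_id = "g2", type = c("exon", "utr3", "cds", "utr5"),
                 start = c(12001L, 12001L, 12201L, 13801L),
                 end = c(14000L, 12200L, 13800L, 14000L))))
  tes <- te_annotation(data.frame(
    te_id = "t1", chrom = "chr1", strand = "+", start = 8001L,
    end = 9000L, te_class = "LTR_Gypsy"))
  list(genome = genome, genes = genes, tes = tes)
}

test_that("flat input gives flat compartment and profile values", {
  toy <- toy_annotation()
  sm <- compute_site_methylation(flat_records(toy$genome, 5L, 5L), r = 0)
  cm <- compartment_methylation(sm, toy$genes, toy$tes,
                                chrom_lengths(toy$genome))
  expect_true(all(abs(cm[n_sites > 0]$ml - 0.5) < 1e-12))
  ## single-exon genes have no intron bases: flagged missing, not zero
  expect_true(all(is.na(cm[compartment == "intron"]$ml)))
  expect_true(all(cm[compartment == "intron"]$n_sites == 0L))

  prof <- metagene_profile(sm, toy$genes)
  expect_true(all(abs(prof[n_sites > 0]$ml - 0.5) < 1e-12))
  tprof <- te_profile(sm, toy$tes)
  expect_true(all(abs(tprof[n_sites > 0]$ml - 0.5) < 1e-12))
})

test_that("bin assignment conserves counts over feature plus flanks", {
  toy <- toy_annotation()
  sm <- compute_site_methylation(flat_records(toy$genome, 3L, 7L), r = 0)
  prof <- metagene_profile(sm, toy$genes)
  g <- toy$genes$genes
  spans <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start - 2000L, g$end + 2000L))
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(sm$chrom, IRanges::IRanges(sm$pos, sm$pos)),
    spans)
  expect_equal(sum(prof$n_sites), length(hits))
  expect_equal(sum(prof$meth), 3 * length(hits))
  expect_equal(sum(prof$unmeth), 7 * length(hits))
})

test_that("minus-strand genes mirror plus-strand genes", {
  toy <- toy_annotation()
  L <- 20000L
  ## mirror genome: reverse complement, with g1 mapped onto a minus gene
  rc <- as.character(Biostrings::reverseComplement(
    toy$genome$seq[["chr1"]]))
  genome2 <- genome_sequence(c(chr1 = rc))
  flip <- function(s, e) c(L - e + 1L, L - s + 1L)
  g1 <- toy$genes$genes[gene_id == "g1"]
  fs <- flip(g1$start, g1$end)
  parts1 <- toy$genes$parts[gene_id == "g1"]
  parts2 <- data.table::data.table(
    gene_id = "g1", type = parts1$type,
    start = L - parts1$end + 1L, end = L - parts1$start + 1L)
  genes2 <- gene_models(
    data.frame(gene_id = "g1", chrom = "chr1", strand = "-",
               start = fs[1], end = fs[2]), parts2)
  genes1 <- gene_models(toy$genes$genes[gene_id == "g1"], parts1)

  ## position-dependent counts, mapped through the mirror
  h <- function(p) (p %% 7L) + 1L
  rec1 <- flat_records(toy$genome)
  rec1[, count_meth := h(pos)]
  rec1[, count_unmeth := 10L - count_meth]
  rec2 <- flat_records(genome2)
  rec2[, count_meth := h(L - pos + 1L)]
  rec2[, count_unmeth := 10L - count_meth]
  p1 <- metagene_profile(compute_site_methylation(rec1, r = 0), genes1)
  p2 <- metagene_profile(compute_site_methylation(rec2, r = 0), genes2)
  expect_equal(p1$ml, p2$ml)
  expect_equal(p1$n_sites, p2$n_sites)
})

test_that("quintile partition sizes, ordering and special class are right", {
  q10 <- quintile_partition(1:10, sprintf("i%02d", 1:10))
  expect_equal(as.integer(table(q10$group)[c("1st", "5th")]), c(2L, 2L))
  expect_equal(q10[id == "i01"]$group, "1st")
  expect_equal(q10[id == "i10"]$group, "5th")

  q8 <- quintile_partition(1:8, sprintf("i%02d", 1:8))
  expect_equal(as.integer(table(q8$group)[c("1st", "2nd", "3rd", "4th",
                                            "5th")]),
               c(2L, 2L, 2L, 1L, 1L))

  ## FPKM < 0.1 goes to the nonexpressed class
  fpkm <- c(0.05, 1, 2, 3, 4, 5, 6)
  qa <- quintile_partition(fpkm, sprintf("g%d", 1:7),
                           special = fpkm < 0.1)
  expect_equal(qa[id == "g1"]$group, "none")

  expect_error(quintile_partition(1:4, letters[1:4]), "at least 5")

  ## all-tie case: stable id order decides
  qt <- quintile_partition(rep(1, 5), letters[5:1])
  expect_equal(qt[order(id)]$group, c("1st", "2nd", "3rd", "4th", "5th"))
})

test_that("grouped profiles reduce to the plain profile for one group", {
  toy <- toy_annotation()
  sm <- compute_site_methylation(flat_records(toy$genome, 4L, 6L), r = 0)
  grouping <- data.table::data.table(id = toy$genes$genes$gene_id,
                                     group = "all")
  gp <- profile_by_group(sm, toy$genes, grouping)
  expect_equal(gp$all, metagene_profile(sm, toy$genes),
               ignore_attr = TRUE)
  expect_warning(
    profile_by_group(sm, toy$genes,
                     data.table::data.table(id = "missing", group = "x")),
    "no genes")
})

test_that("expression-by-methylation grouping applies the coverage rules", {
  region_ml <- data.table::data.table(
    gene_id = sprintf("g%02d", 1:10),
    ml = c(NA, 0.05, seq(0.1, 0.8, length.out = 8)),
    n_sites = c(0L, 3L, rep(20L, 8)),
    n_mc = c(0L, 1L, rep(5L, 8)))
  expr <- data.table::data.table(gene_id = sprintf("g%02d", 1:10),
                                 fpkm = c(1, 2, 8, 7, 6, 5, 4, 3, 2, 1))
  res <- expression_by_methylation_group(expr, region_ml, min_sites = 5L)
  expect_equal(res$n_excluded, 1L)                     # no covered sites
  expect_equal(res$groups[gene_id == "g02"]$group, "unmethylated")
  expect_equal(nrow(res$groups), 9L)
  expect_setequal(unique(res$groups$group),
                  c("unmethylated", "1st", "2nd", "3rd", "4th", "5th"))
})

test_that("TE length quintiles split per class and recover level trends", {
  sim <- small_sim()
  called <- small_called()
  res <- te_length_quintiles(sim$tes, called$control)
  expect_true(all(res$group %in% c("1st", "2nd", "3rd", "4th", "5th")))
  ## quintile ordering by construction: 1st shortest
  for (cls in unique(res$te_class)) {
    sub <- unique(res[te_class == cls, .(group, mean_length)])
    sub <- sub[order(group)]
    expect_true(all(diff(sub$mean_length) >= 0))
  }
})

test_that("simulated compartment ordering is recovered from counts", {
  sim <- small_sim()
  called <- small_called()
  cm <- compartment_methylation(called$control, sim$genes, sim$tes,
                                sim$config$chrom_lengths,
                                exclude_chroms = "lambda")
  cg <- function(comp) cm[compartment == comp & context == "CG"]$ml
  expect_gt(cg("te"), cg("promoter"))
  expect_gt(cg("promoter"), cg("cds"))
  expect_gt(cg("cds"), cg("utr5"))

  ## TE-body hypermethylation shows up in the TE profile
  tprof <- te_profile(called$control, sim$tes)
  cg_body <- tprof[segment == "body" & context == "CG"]
  cg_flank <- tprof[segment != "body" & context == "CG"]
  expect_gt(sum(cg_body$meth) / sum(cg_body$meth + cg_body$unmeth),
            sum(cg_flank$meth) / sum(cg_flank$meth + cg_flank$unmeth))
})
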