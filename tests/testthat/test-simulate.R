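test_that("the simulator is byte-deterministic under a fixed seed", {
  cfg <- small_config()
  sim1 <- small_sim()
  sim2 <- simulate_methylome(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(sim1$genome, f1)
  write_fasta(sim2$genome, f2)
  expect_equal(tools::md5sum(f1)[[1]], tools::md5sum(f2)[[1]])
  expect_identical(sim1$counts$control[[1]], sim2$counts$control[[1]])
  expect_identical(sim1$planted, sim2$planted)
  expect_identical(sim1$expression, sim2$expression)
})

test_that("genome construction satisfies the configured composition", {
  sim <- small_sim()
  cfg <- small_config()
  expect_equal(nrow(sim$genes$genes), cfg$gene_count)
  te_bp <- sum(sim$tes$end - sim$tes$start + 1L)
  frac <- te_bp / sum(cfg$chrom_lengths)
  expect_lt(abs(frac - cfg$te_fraction), 0.02 * cfg$te_fraction + 0.01)
  ## genes and TEs do not overlap
  gr <- c(GenomicRanges::GRanges(sim$genes$genes$chrom,
                                 IRanges::IRanges(sim$genes$genes$start,
                                                  sim$genes$genes$end)),
          GenomicRanges::GRanges(sim$tes$chrom,
                                 IRanges::IRanges(sim$tes$start,
                                                  sim$tes$end)))
  expect_equal(sum(IRanges::width(GenomicRanges::reduce(gr))),
               sum(IRanges::width(gr)))
  ## spike-in chromosome appended and flagged
  expect_equal(sim$genome$spike_in_chrom, "lambda")
  expect_equal(unname(chrom_lengths(sim$genome)["lambda"]),
               cfg$spike_in_length)
})

test_that("TE class sampling follows the configured mix", {
  cfg <- simulation_config(seed = 5L, chrom_lengths = c(chr1 = 200000L),
                           gene_count = 5L, te_fraction = 0.4,
                           te_class_mix = c(LTR_Gypsy = 2, LTR_Copia = 1),
                           n_dmrs = 0L, spike_in_length = 5000L)
  sim <- simulate_genome(cfg)
  n <- nrow(sim$tes)
  k <- sum(sim$tes$te_class == "LTR_Gypsy")
  ## binomial 3-sigma band around 2/3
  p <- 2 / 3
  expect_lt(abs(k / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("true methylation respects compartments and the spike-in", {
  sim <- small_sim()
  truth <- sim$truth_control
  expect_true(all(truth[chrom == "lambda"]$ml == 0))
  expect_true(all(truth$ml >= 0 & truth$ml <= 1))
  ## configured compartment ordering is realized (TE CG > exon/cds CG)
  mte <- mean(truth[compartment == "te" & context == "CG"]$ml)
  mcds <- mean(truth[compartment == "cds" & context == "CG"]$ml)
  expect_gt(mte, mcds)
})

test_that("a point-mass configuration gives exact levels everywhere", {
  lv <- list(CG = context_level(1, 0.5, Inf),
             CHG = context_level(1, 0.5, Inf),
             CHH = context_level(1, 0.5, Inf))
  cfg <- simulation_config(
    seed = 3L, chrom_lengths = c(chr1 = 30000L), gene_count = 4L,
    te_fraction = 0.2, n_dmrs = 0L, spike_in_length = 2000L,
    context_levels = stats::setNames(
      rep(list(lv), 8L),
      c("te", "promoter", "utr5", "cds", "intron", "utr3",
        "downstream", "intergenic")))
  sim <- simulate_genome(cfg)
  truth <- assign_true_methylation(sim, cfg)
  expect_true(all(truth[chrom != "lambda"]$ml == 0.5))
})

test_that("planting shifts, clamps and leaves the rest untouched", {
  lv <- list(CG = context_level(1, 0.5, Inf),
             CHG = context_level(1, 0.5, Inf),
             CHH = context_level(1, 0.5, Inf))
  base_cfg <- function(n_dmrs, effect) simulation_config(
    seed = 3L, chrom_lengths = c(chr1 = 60000L), gene_count = 4L,
    te_fraction = 0.15, n_dmrs = n_dmrs, dmr_effect = effect,
    dmr_direction = "hyper", spike_in_length = 2000L,
    context_levels = stats::setNames(
      rep(list(lv), 8L),
      c("te", "promoter", "utr5", "cds", "intron", "utr3",
        "downstream", "intergenic")))

  ## n_dmrs = 0: conditions identical
  cfg0 <- base_cfg(0L, 0.4)
  sim0 <- simulate_genome(cfg0)
  tr0 <- assign_true_methylation(sim0, cfg0)
  pl0 <- plant_dmrs(tr0, sim0, cfg0)
  expect_identical(pl0$truth_case$ml, tr0$ml)
  expect_equal(nrow(pl0$planted), 0L)

  ## +0.4 on 0.5 gives 0.9 inside, 0.5 outside
  cfg <- base_cfg(3L, 0.4)
  sim <- simulate_genome(cfg)
  tr <- assign_true_methylation(sim, cfg)
  pl <- plant_dmrs(tr, sim, cfg)
  expect_equal(nrow(pl$planted), 3L)
  inside <- rep(FALSE, nrow(tr))
  for (i in seq_len(3L))
    inside <- inside | (tr$chrom == pl$planted$chrom[i] &
                          tr$pos >= pl$planted$start[i] &
                          tr$pos <= pl$planted$end[i] &
                          tr$context == "CG")
  expect_true(all(pl$truth_case$ml[inside & tr$chrom != "lambda"] == 0.9))
  expect_identical(pl$truth_case$ml[!inside], tr$ml[!inside])

  ## +0.8 on 0.5 clamps at 1.0
  cfg8 <- base_cfg(2L, 0.8)
  sim8 <- simulate_genome(cfg8)
  tr8 <- assign_true_methylation(sim8, cfg8)
  pl8 <- plant_dmrs(tr8, sim8, cfg8)
  in8 <- tr8$chrom == pl8$planted$chrom[1] &
    tr8$pos >= pl8$planted$start[1] & tr8$pos <= pl8$planted$end[1] &
    tr8$context == "CG"
  expect_true(all(pl8$truth_case$ml[in8] == 1))
})

test_that("count simulation follows the coverage and noise model", {
  sim <- small_sim()
  cfg <- small_config()
  ## same (seed, condition, replicate) gives identical reports
  c1 <- simulate_counts(sim$truth_control, cfg, 1L, 1L)
  c2 <- simulate_counts(sim$truth_control, cfg, 1L, 1L)
  expect_identical(c1, c2)
  expect_false(identical(
    c1, simulate_counts(sim$truth_control, cfg, 1L, 2L)))

  ## fully methylated, r = 0: no unmethylated reads anywhere
  tr <- data.table::copy(sim$truth_control)[chrom != "lambda"]
  tr[, ml := 1]
  cfg_r0 <- small_config()
  cfg_r0$nonconversion_rate <- 0
  cc <- simulate_counts(tr, cfg_r0, 1L, 1L)
  expect_true(all(cc$count_unmeth == 0L))

  ## unmethylated at r = 0.0012: pooled observed level ~ r (3 sigma)
  lam <- sim$truth_control[chrom == "lambda"]
  cl <- simulate_counts(lam, cfg, 1L, 1L)
  tot <- sum(cl$count_meth + cl$count_unmeth)
  obs <- sum(cl$count_meth) / tot
  expect_lt(abs(obs - 0.0012), 3 * sqrt(0.0012 * 0.9988 / tot))
})

test_that("pooled observed ML converges to ML(1-r) + r per context", {
  sim <- small_sim()
  cfg <- small_config()
  r <- cfg$nonconversion_rate
  pooled <- pool_replicates(sim$counts$control)
  joined <- merge(pooled,
                  sim$truth_control[, .(chrom, pos, strand, ml)],
                  by = c("chrom", "pos", "strand"))
  for (ctx in c("CG", "CHG", "CHH")) {
    sub <- joined[context == ctx & chrom != "lambda"]
    tot <- sum(sub$count_meth + sub$count_unmeth)
    obs <- sum(sub$count_meth) / tot
    expected <- sum((sub$ml * (1 - r) + r) *
                      (sub$count_meth + sub$count_unmeth)) / tot
    expect_lt(abs(obs - expected), 3 * sqrt(0.25 / tot) + 1e-4)
  }
})

test_that("expression simulation realizes the configured fractions", {
  cfg <- small_config()
  sim <- small_sim()
  ## DE fraction 0: all labels none
  cfg0 <- small_config()
  cfg0$expression_model$de_fraction <- 0
  e0 <- simulate_expression(sim, cfg0)
  expect_true(all(e0$de_label == "none"))

  ## nonexpressed fraction: binomial 3-sigma check at n = 1000
  cfg2 <- simulation_config(seed = 8L, chrom_lengths = c(chr1 = 900000L),
                            gene_count = 1000L, te_fraction = 0.05,
                            n_dmrs = 0L, spike_in_length = 2000L,
                            gene_structure = list(exon_count_mean = 1,
                                                  exon_length_mean = 120,
                                                  utr5_length = 40,
                                                  utr3_length = 40),
                            expression_model = list(
                              nonexpressed_fraction = 0.2))
  sim2 <- simulate_genome(cfg2)
  e2 <- simulate_expression(sim2, cfg2)
  n_low <- sum(e2$fpkm_control < 0.1)
  expect_lt(abs(n_low - 200), 3 * sqrt(1000 * 0.2 * 0.8) + 1)

  ## promoter-DMR/expression coupling enriches concordant labels
  cfg3 <- simulation_config(seed = 15L, chrom_lengths = c(chr1 = 500000L),
                            gene_count = 60L, te_fraction = 0.05,
                            n_dmrs = 30L, dmr_compartment = "promoter",
                            dmr_length_range = c(300L, 600L),
                            spike_in_length = 2000L,
                            gene_structure = list(exon_count_mean = 2,
                                                  exon_length_mean = 150,
                                                  utr5_length = 60,
                                                  utr3_length = 60),
                            expression_model = list(coupling = TRUE,
                                                    coupling_prob = 0.9,
                                                    de_fraction = 0.05))
  sim3 <- simulate_genome(cfg3)
  tr3 <- assign_true_methylation(sim3, cfg3)
  pl3 <- plant_dmrs(tr3, sim3, cfg3)
  e3 <- simulate_expression(sim3, cfg3, planted = pl3$planted)
  reg <- bsmeth:::gene_region_table(sim3$genes, 2000L, 2000L)
  prom <- reg[reg$region == "promoter"]
  hit <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(pl3$planted$chrom,
                           IRanges::IRanges(pl3$planted$start,
                                            pl3$planted$end)),
    GenomicRanges::GRanges(prom$chrom,
                           IRanges::IRanges(prom$start, prom$end)))
  hyper_genes <- unique(prom$gene_id[S4Vectors::subjectHits(hit)][
    pl3$planted$direction[S4Vectors::queryHits(hit)] == "hyper"])
  expect_gt(length(hyper_genes), 3L)
  tab <- table(touched = e3$gene_id %in% hyper_genes,
               down = e3$de_label == "down")
  or <- (tab[2, 2] / max(1, tab[2, 1])) / (tab[1, 2] / tab[1, 1])
  expect_gt(or, 1)
})
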