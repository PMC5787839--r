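test_that("DMG x DEG overlap counts follow set arithmetic", {
  dmf <- data.table::data.table(
    feature_id = c("a", "b", "c"), region = "promoter", context = "CG",
    status = c("hyper", "hyper", "hypo"), n_dmrs = 1L)
  expr <- data.table::data.table(
    gene_id = c("a", "b", "c", "d"),
    fpkm = 1, de_label = c("none", "down", "up", "down"))
  ov <- overlap_dmg_deg(dmf, expr)
  expect_equal(unname(ov$counts["hyper_down"]), 1L)
  expect_equal(ov$genes$hyper_down, "b")
  expect_equal(unname(ov$counts["hypo_up"]), 1L)
  expect_equal(unname(ov$counts["hyper_up"]), 0L)

  ## disjoint sets: all four counts zero
  dmf0 <- data.table::data.table(feature_id = "a", region = "body",
                                 context = "CG", status = "hyper",
                                 n_dmrs = 1L)
  expr0 <- data.table::data.table(gene_id = c("a", "b"), fpkm = 1,
                                  de_label = "none")
  expect_true(all(overlap_dmg_deg(dmf0, expr0)$counts == 0L))

  ## annotation mismatch is refused
  dmf_bad <- data.table::data.table(feature_id = c("x", "y", "z"),
                                    region = "body", context = "CG",
                                    status = "hyper", n_dmrs = 1L)
  expect_error(overlap_dmg_deg(dmf_bad, expr), "annotation")
})

test_that("Venn region counts partition the union", {
  v <- venn_counts(list(A = c(1, 2, 3), B = c(2, 3, 4)))
  expect_equal(v[region == "A"]$count, 1L)
  expect_equal(v[region == "B"]$count, 1L)
  expect_equal(v[region == "A&B"]$count, 2L)
  expect_equal(sum(v$count), 4L)

  v2 <- venn_counts(list(A = 1:3, B = 1:3))
  expect_equal(v2[region == "A&B"]$count, 3L)
  expect_equal(v2[region == "A"]$count, 0L)

  v3 <- venn_counts(list(A = 1, B = 2, C = 3))
  expect_equal(sum(v3$count > 0), 3L)
  expect_true(all(v3[grepl("&", region)]$count == 0L))
})

test_that("Wilcoxon p matches full enumeration for small tie-free samples", {
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(3, 4)), 1 / 3,
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)

  set.seed(14)
  for (i in 1:20) {
    nx <- sample(2:5, 1L); ny <- sample(2:5, 1L)
    v <- sample(100L, nx + ny)
    x <- v[seq_len(nx)]; y <- v[-seq_len(nx)]
    expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_enumerate(x, y),
                 tolerance = 1e-12)
  }

  ## normal approximation is close to exact at the n = 8 crossover
  set.seed(15)
  x <- rnorm(8); y <- rnorm(9) + 0.5
  approx_p <- wilcoxon_rank_sum(x, y)           # min(n) = 8 -> exact
  big <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE)$p.value)
  expect_lt(abs(approx_p - big), 0.01)
})

test_that("group comparison reports quartiles, whiskers and Wilcoxon p", {
  gc <- group_expression_comparison(1:9, 1:9, numeric())
  all_row <- gc[group == "all"]
  expect_equal(all_row$median, 5)
  expect_equal(all_row$q1, 2.5)
  expect_equal(all_row$q3, 7.5)
  ## identical distribution: p = 1
  expect_equal(gc[group == "hyper"]$wilcoxon_p, 1)
  expect_equal(gc[group == "hypo"]$n, 0L)
  expect_false(gc[group == "hypo"]$reliable)

  ## whiskers stop at the most extreme point within 1.5 IQR
  v <- c(1:9, 100)
  gc2 <- group_expression_comparison(v, v, v)
  row <- gc2[group == "all"]
  iqr <- row$q3 - row$q1
  expect_lte(row$whisker_hi, row$q3 + 1.5 * iqr)
  expect_equal(row$whisker_hi, max(v[v <= row$q3 + 1.5 * iqr]))
})

test_that("comparative Ct arithmetic gives 2^-ddCt", {
  expect_equal(relative_expression_ddct(20, 20, 20, 20), 1)
  expect_equal(relative_expression_ddct(20, 22, 24, 24), 4)
  expect_equal(relative_expression_ddct(25, 20, 24, 20), 0.5)
  expect_error(relative_expression_ddct(-1, 20, 20, 20), "positive")
})

test_that("the integration table covers every gene exactly once", {
  sim <- small_sim()
  called <- small_called()
  dmr <- call_dmrs(called$case, called$control, sim$config$chrom_lengths)
  dmf <- assign_dmr_features(dmr$dmrs, sim$genes)
  integ <- build_integration_table(dmf, sim$expression, sim$genes)
  expect_equal(sort(integ$gene_id), sort(sim$genes$genes$gene_id))
  expect_false(anyDuplicated(integ$gene_id) > 0)
  expect_true(all(integ$status_any %in% c("hyper", "hypo", "both",
                                          "none")))
  expect_true(all(is.finite(integ$log2fc)))
  ## log2fc definition
  e1 <- sim$expression[1]
  expect_equal(integ[gene_id == e1$gene_id]$log2fc,
               log2((e1$fpkm_case + 0.01) / (e1$fpkm_control + 0.01)))
})
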