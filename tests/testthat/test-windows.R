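test_that("window geometry follows the trailing-window rule", {
  ## 6000 bp chromosome: six full 3000/600 windows, no trailing sliver
  ws <- window_starts(6000L, 3000L, 600L)
  expect_equal(ws$start, c(1L, 601L, 1201L, 1801L, 2401L, 3001L))
  expect_equal(ws$end[6], 6000L)

  ## leftover shorter than half a window is dropped
  expect_equal(nrow(window_starts(6200L, 3000L, 600L)), 6L)
  ws8 <- window_starts(7600L, 3000L, 600L)
  expect_equal(nrow(ws8), 8L)
  expect_equal(utils::tail(ws8, 1L)$end, 7200L)
  ## with non-overlapping windows a leftover of at least half a window
  ## is kept as a truncated terminal window
  ws2 <- window_starts(7600L, 3000L, 3000L)
  expect_equal(ws2$start, c(1L, 3001L, 6001L))
  expect_equal(utils::tail(ws2, 1L)$end, 7600L)

  ## short chromosomes
  expect_equal(window_starts(2000L, 3000L, 600L),
               data.table::data.table(start = 1L, end = 2000L))
  expect_equal(nrow(window_starts(1000L, 3000L, 600L)), 0L)
  expect_error(window_starts(5000L, 3000L, 700L), "multiple")
})

test_that("window ML is count-pooled, with undefined windows flagged", {
  rec <- data.table::data.table(
    chrom = "chr1", pos = c(100L, 200L, 300L), strand = "+",
    count_meth = c(10L, 10L, 10L), count_unmeth = c(90L, 90L, 90L),
    context = "CG", trinucleotide = "CGA")
  sm <- compute_site_methylation(rec, r = 0)
  w <- window_summarize(sm, c(chr1 = 3000L), window_size = 3000L,
                        step = 600L)
  cg1 <- w[context == "CG" & start == 1L]
  expect_equal(cg1$meth, 30)
  expect_equal(cg1$unmeth, 270)
  expect_equal(cg1$ml, 0.1)
  expect_true(is.na(w[context == "CHH" & start == 1L]$ml))
})

test_that("window sums match a brute-force per-window recomputation", {
  set.seed(21)
  n <- 400L
  sm <- compute_site_methylation(data.table::data.table(
    chrom = "chr1", pos = sort(sample.int(9000L, n)), strand = "+",
    count_meth = rbinom(n, 10, 0.4),
    count_unmeth = rbinom(n, 10, 0.6),
    context = sample(c("CG", "CHG", "CHH"), n, replace = TRUE),
    trinucleotide = "CNN"), r = 0, min_coverage = 1L)
  w <- window_summarize(sm, c(chr1 = 9000L), window_size = 1000L,
                        step = 100L, correct = FALSE)
  ws <- window_starts(9000L, 1000L, 100L)
  for (i in sample.int(nrow(ws), 25L)) {
    for (ctx in c("CG", "CHG", "CHH")) {
      inwin <- sm[covered & context == ctx & pos >= ws$start[i] &
                    pos <= ws$end[i]]
      row <- w[context == ctx & start == ws$start[i]]
      expect_equal(row$meth, sum(inwin$count_meth))
      expect_equal(row$unmeth, sum(inwin$count_unmeth))
      expect_equal(row$n_sites, nrow(inwin))
      if (nrow(inwin))
        expect_equal(row$ml,
                     sum(inwin$count_meth) /
                       sum(inwin$count_meth + inwin$count_unmeth))
    }
  }
})

test_that("global summary percentages and proportions are consistent", {
  sim_called <- small_called()
  gs <- global_summary(sim_called$control[chrom != "lambda"],
                       c(chr1 = 120000L))
  expect_true(all(gs$pct_methylation >= 0 & gs$pct_methylation <= 100))
  expect_equal(sum(gs$relative_mc_proportion), 100, tolerance = 1e-9)
  ## density counts add up to the mC total
  expect_equal(sum(gs$density$n_mc), gs$n_mc)

  ## degenerate case: only CG methylated
  rec <- data.table::data.table(
    chrom = "chr1", pos = c(10L, 20L), strand = "+",
    count_meth = c(10L, 0L), count_unmeth = c(0L, 10L),
    context = c("CG", "CHH"), trinucleotide = c("CGA", "CAA"))
  smc <- call_methylated_sites(compute_site_methylation(rec, r = 0.001))
  gs2 <- global_summary(smc, c(chr1 = 1000L))
  expect_equal(unname(gs2$relative_mc_proportion), c(100, 0, 0))

  expect_error(global_summary(smc[0], c(chr1 = 1000L)), "no covered")
})
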