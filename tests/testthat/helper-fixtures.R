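## Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

## Small two-condition simulation with planted CG DMRs in a moderately
## methylated unimodal intergenic background (headroom for +/-0.4 shifts).
small_config <- function(seed = 11L) {
  simulation_config(
    seed = seed,
    chrom_lengths = c(chr1 = 120000L),
    gene_count = 20L,
    te_fraction = 0.25,
    spike_in_length = 20000L,
    n_dmrs = 4L,
    dmr_effect = 0.4,
    context_levels = list(
      intergenic = list(CG = context_level(1, 0.35, 20),
                        CHG = context_level(0.36, 0.65, 10),
                        CHH = context_level(0.07, 0.38, 8)))
  )
}

small_sim <- function() {
  if (is.null(.fixtures$sim)) .fixtures$sim <- simulate_methylome(small_config())
  .fixtures$sim
}

## Pooled, corrected, mC-called site methylation per condition.
small_called <- function() {
  if (is.null(.fixtures$called)) {
    sim <- small_sim()
    r <- estimate_nonconversion(pool_replicates(sim$counts$control),
                                "lambda")$r
    .fixtures$called <- lapply(sim$counts, function(reps)
      call_methylated_sites(compute_site_methylation(pool_replicates(reps),
                                                     r = r)))
  }
  .fixtures$called
}

## Cytosine records with constant counts at every site of a genome
## (flat methylation level meth/(meth+unmeth)).
flat_records <- function(genome, meth = 5L, unmeth = 5L) {
  sites <- classify_contexts(genome)
  sites[, `:=`(count_meth = meth, count_unmeth = unmeth)]
  sites[, .(chrom, pos, strand, count_meth, count_unmeth, context,
            trinucleotide)]
}

## Fraction of planted DMRs overlapped by a called DMR of matching
## context and direction.
planted_recall <- function(dmrs, planted) {
  if (nrow(planted) == 0L) return(NA_real_)
  hits <- vapply(seq_len(nrow(planted)), function(i) {
    any(dmrs$chrom == planted$chrom[i] &
          dmrs$context == planted$context[i] &
          dmrs$status == planted$direction[i] &
          dmrs$start <= planted$end[i] &
          dmrs$end >= planted$start[i])
  }, logical(1))
  mean(hits)
}

## Independent brute-force context scan: regex over the sequence and its
## reverse complement (positions mapped back to plus-strand coordinates).
brute_force_contexts <- function(seq_string, chrom = "chr") {
  scan_one <- function(s, strand) {
    L <- nchar(s)
    hits <- list()
    pats <- c(CG = "(?=CG[ACGT])", CHG = "(?=C[ACT]G)",
              CHH = "(?=C[ACT][ACT])")
    ## a CG two bases from the end still has a defined context even
    ## though only one downstream base exists past the G -- the CG
    ## dinucleotide itself decides; handle it with a separate pattern
    pats_cg_end <- "(?=CG)"
    for (ctx in names(pats)) {
      mm <- gregexpr(if (ctx == "CG") pats_cg_end else pats[[ctx]], s,
                     perl = TRUE)[[1]]
      pp <- as.integer(mm[mm > 0])
      if (ctx == "CG") pp <- pp[pp <= L - 2L]  # need two downstream bases
      if (length(pp) == 0L) next
      tri <- substring(s, pp, pp + 2L)
      keep <- !grepl("N", tri, fixed = TRUE)
      pp <- pp[keep]; tri <- tri[keep]
      if (length(pp) == 0L) next
      hits[[ctx]] <- data.table::data.table(
        pos_local = pp, context = ctx, trinucleotide = tri)
    }
    out <- data.table::rbindlist(hits)
    if (nrow(out) == 0L) return(out)
    if (strand == "+") {
      out[, `:=`(chrom = chrom, pos = pos_local, strand = "+")]
    } else {
      out[, `:=`(chrom = chrom, pos = L - pos_local + 1L, strand = "-")]
    }
    out[, pos_local := NULL]
    out[]
  }
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(seq_string)))
  res <- rbind(scan_one(seq_string, "+"), scan_one(rc, "-"))
  data.table::setorder(res, pos, strand)
  res[, .(chrom, pos, strand, context, trinucleotide)]
}

## Random sequence with embedded N runs (ambiguous/assembly-gap bases).
with_n_runs_sequence <- function(seed, len = 10000L) {
  set.seed(seed)
  ch <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  for (k in seq_len(3L)) {
    s <- sample.int(len - 50L, 1L)
    ch[s:(s + sample.int(30L, 1L))] <- "N"
  }
  paste(ch, collapse = "")
}

## Independent BH step-up computation.
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o] * m / seq_len(m)
  qs <- rev(cummin(rev(ranked)))
  q <- numeric(m)
  q[o] <- pmin(1, qs)
  q
}

## Exact two-sided Wilcoxon rank-sum p by full enumeration of all
## choose(nx+ny, nx) rank assignments (tie-free inputs).
wilcoxon_enumerate <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(nx + ny, nx)
  ws <- apply(combos, 2L, function(ix) sum(ix) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}
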