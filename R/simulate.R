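## Synthetic methylome generator with full ground truth.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## One gene's sub-feature layout in local 5'->3' coordinates.
## Returns list(length, parts = data.table(type, start, end)).
build_gene_layout <- function(gs) {
  k <- 1L + stats::rpois(1L, max(0, gs$exon_count_mean - 1))
  elen <- pmax(30L, stats::rpois(k, gs$exon_length_mean))
  ilen <- if (k > 1L) pmax(30L, stats::rpois(k - 1L, gs$intron_length_mean))
          else integer()
  u5 <- as.integer(gs$utr5_length)
  u3 <- as.integer(gs$utr3_length)
  total <- u5 + sum(elen) + sum(ilen) + u3
  cds <- vector("list", k)
  cursor <- u5
  exons <- vector("list", k)
  for (i in seq_len(k)) {
    s <- cursor + 1L
    e <- cursor + elen[i]
    cds[[i]] <- c(s, e)
    ## terminal exons absorb the adjacent UTR
    exons[[i]] <- c(if (i == 1L) 1L else s,
                    if (i == k) e + u3 else e)
    cursor <- e + if (i < k) ilen[i] else 0L
  }
  parts <- rbind(
    data.table::data.table(type = "utr5", start = 1L, end = u5),
    data.table::data.table(type = "cds",
                           start = vapply(cds, `[`, integer(1), 1L),
                           end = vapply(cds, `[`, integer(1), 2L)),
    data.table::data.table(type = "utr3", start = total - u3 + 1L,
                           end = total),
    data.table::data.table(type = "exon",
                           start = vapply(exons, `[`, integer(1), 1L),
                           end = vapply(exons, `[`, integer(1), 2L))
  )
  list(length = total, parts = parts)
}

## local 5'->3' interval -> genomic, given gene start/end and strand
local_to_genomic <- function(parts, gstart, gend, strand) {
  if (strand == "+") {
    data.table::data.table(type = parts$type,
                           start = gstart + parts$start - 1L,
                           end = gstart + parts$end - 1L)
  } else {
    data.table::data.table(type = parts$type,
                           start = gend - parts$end + 1L,
                           end = gend - parts$start + 1L)
  }
}

#' Simulate an annotated genome
#'
#' Generates random chromosome sequences, places non-overlapping genes
#' (with UTR/CDS/intron structure) and transposable elements, and appends
#' an unmethylated lambda-sized spike-in chromosome. TE lengths are drawn
#' log-normally until the configured genome fraction is reached (the last
#' element is trimmed to hit it exactly); classes follow the configured
#' mix. Fails with a capacity error when the requested features cannot be
#' packed.
#'
#' @param config a [simulation_config()].
#' @return list with `genome` ([genome_sequence()]), `genes`
#'   ([gene_models()]), `tes` ([te_annotation()]).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(derive_seed(config$seed, 1L), {
    cl <- config$chrom_lengths
    total <- sum(cl)
    gs <- config$gene_structure

    layouts <- replicate(config$gene_count, build_gene_layout(gs),
                         simplify = FALSE)
    gene_len <- vapply(layouts, `[[`, numeric(1), "length")

    te_target <- round(config$te_fraction * total)
    te_len <- integer()
    while (sum(te_len) < te_target) {
      draw <- pmax(80L, as.integer(round(stats::rlnorm(
        64L, config$te_length_meanlog, config$te_length_sdlog))))
      te_len <- c(te_len, draw)
    }
    over <- which(cumsum(te_len) >= te_target)[1L]
    te_len <- te_len[seq_len(over)]
    te_len[over] <- te_len[over] - (sum(te_len) - te_target)
    te_len <- te_len[te_len > 0L]

    ## reserve intergenic host intervals for planted DMRs (with a margin
    ## so the interval is not swallowed by promoter/downstream flanks)
    dmr_margin <- 2000L
    n_hosts <- if (config$dmr_compartment == "intergenic") config$n_dmrs
               else 0L
    host_len <- if (n_hosts > 0L)
      as.integer(round(stats::runif(n_hosts, config$dmr_length_range[1],
                                    config$dmr_length_range[2])))
    else integer()

    feat <- data.table::data.table(
      kind = c(rep("gene", length(gene_len)), rep("te", length(te_len)),
               rep("dmr", n_hosts)),
      idx = c(seq_along(gene_len), seq_along(te_len), seq_len(n_hosts)),
      len = c(gene_len, te_len, host_len + 2L * dmr_margin))
    if (sum(feat$len) > 0.95 * total)
      stop("capacity error: requested genes + TEs occupy more than 95% ",
           "of the genome; enlarge chrom_lengths", call. = FALSE)
    feat <- feat[sample(.N)]

    ## greedy assignment to the chromosome with most free space
    free <- as.numeric(cl)
    feat[, chrom := {
      ch <- character(.N)
      for (i in seq_len(.N)) {
        j <- which.max(free)
        if (free[j] < len[i])
          stop("capacity error: cannot place a feature of ", len[i],
               " bp; enlarge chrom_lengths", call. = FALSE)
        ch[i] <- names(cl)[j]
        free[j] <- free[j] - len[i]
      }
      ch
    }]

    gene_rows <- list(); part_rows <- list(); te_rows <- list()
    host_rows <- list()
    te_classes <- sample(names(config$te_class_mix),
                         length(te_len), replace = TRUE,
                         prob = config$te_class_mix)
    for (cn in names(cl)) {
      sub <- feat[chrom == cn]
      nfeat <- nrow(sub)
      if (nfeat == 0L) next
      slack <- cl[[cn]] - sum(sub$len)
      gaps <- as.vector(stats::rmultinom(1L, slack, rep(1, nfeat + 1L)))
      cursor <- 0L
      for (i in seq_len(nfeat)) {
        cursor <- cursor + gaps[i]
        fstart <- cursor + 1L
        fend <- cursor + sub$len[i]
        cursor <- fend
        strand <- sample(c("+", "-"), 1L)
        if (sub$kind[i] == "gene") {
          gid <- sprintf("g%05d", sub$idx[i])
          gene_rows[[length(gene_rows) + 1L]] <- data.table::data.table(
            gene_id = gid, chrom = cn, strand = strand,
            start = fstart, end = fend)
          pr <- local_to_genomic(layouts[[sub$idx[i]]]$parts,
                                 fstart, fend, strand)
          pr[, gene_id := gid]
          part_rows[[length(part_rows) + 1L]] <- pr
        } else if (sub$kind[i] == "te") {
          te_rows[[length(te_rows) + 1L]] <- data.table::data.table(
            te_id = sprintf("te%05d", sub$idx[i]), chrom = cn,
            strand = strand, start = fstart, end = fend,
            te_class = te_classes[sub$idx[i]])
        } else {
          host_rows[[length(host_rows) + 1L]] <- data.table::data.table(
            idx = sub$idx[i], chrom = cn,
            start = fstart + dmr_margin,
            end = fstart + dmr_margin + host_len[sub$idx[i]] - 1L)
        }
      }
    }

    seqs <- vapply(names(cl), function(cn) random_dna(cl[[cn]]),
                   character(1))
    seqs[config$spike_in_name] <- random_dna(config$spike_in_length)
    genome <- genome_sequence(seqs, spike_in_chrom = config$spike_in_name)

    genes <- gene_models(data.table::rbindlist(gene_rows),
                         data.table::rbindlist(part_rows))
    tes <- te_annotation(data.table::rbindlist(te_rows))
    dmr_hosts <- if (length(host_rows)) {
      h <- data.table::rbindlist(host_rows)
      data.table::setorder(h, idx)
      h[, idx := NULL]
      h[]
    } else NULL
    list(genome = genome, genes = genes, tes = tes, dmr_hosts = dmr_hosts)
  })
}

#' Assign true per-site methylation levels (condition 1)
#'
#' Classifies every cytosine of the simulated genome, assigns it to its
#' unique compartment (TE > gene sub-feature > promoter/downstream >
#' intergenic), and draws its true methylation level from the
#' compartment-and-context zero-inflated Beta of the configuration. All
#' spike-in sites get a true level of exactly 0 (unmethylated control).
#'
#' @param sim output of [simulate_genome()].
#' @param config the [simulation_config()].
#' @return `data.table` of class `methylome_truth` with `chrom, pos,
#'   strand, context, trinucleotide, compartment, ml`; the nonconversion
#'   rate is stored in the `r_true` attribute.
#' @export
assign_true_methylation <- function(sim, config) {
  sites <- classify_contexts(sim$genome)
  main_len <- config$chrom_lengths
  part <- compartment_partition(sim$genes, sim$tes, main_len)
  sites[, compartment := "spike_in"]
  main <- sites$chrom != config$spike_in_name
  sites[main == TRUE,
        compartment := site_compartments(sites[main == TRUE], part)]
  sites[, ml := 0]
  with_seed(derive_seed(config$seed, 2L), {
    for (comp in names(config$context_levels)) {
      for (ctx in CONTEXTS) {
        lvl <- config$context_levels[[comp]][[ctx]]
        idx <- which(sites$compartment == comp & sites$context == ctx)
        if (length(idx) == 0L) next
        z <- stats::rbinom(length(idx), 1L, lvl$p_meth)
        vals <- if (is.infinite(lvl$conc)) {
          z * lvl$mean  # degenerate Beta: point mass at the mean
        } else {
          a <- lvl$mean * lvl$conc
          b <- (1 - lvl$mean) * lvl$conc
          z * stats::rbeta(length(idx), a, b)
        }
        sites[idx, ml := vals]
      }
    }
  })
  data.table::setattr(sites, "r_true", config$nonconversion_rate)
  data.table::setattr(sites, "class",
                      c("methylome_truth", class(sites)))
  sites[]
}

#' Plant DMRs into a second condition
#'
#' Samples non-overlapping intervals inside the configured host
#' compartment, shifts the true methylation of the chosen context inside
#' each interval by the configured effect (clamped to \[0, 1\]) and leaves
#' every other site identical to condition 1. With direction `"both"`,
#' planted DMRs alternate hyper/hypo.
#'
#' @param truth condition-1 truth from [assign_true_methylation()].
#' @param sim output of [simulate_genome()].
#' @param config the [simulation_config()].
#' @return list with `truth_case` (condition-2 truth) and `planted`
#'   (`data.table` chrom/start/end/context/direction/effect).
#' @export
plant_dmrs <- function(truth, sim, config) {
  truth_case <- data.table::copy(truth)
  n <- config$n_dmrs
  planted <- data.table::data.table(
    chrom = character(), start = integer(), end = integer(),
    context = character(), direction = character(), effect = numeric())
  if (n == 0L)
    return(list(truth_case = truth_case, planted = planted))
  if (!is.null(sim$dmr_hosts) && config$dmr_compartment == "intergenic") {
    ## host intervals were reserved during genome packing
    hosts <- sim$dmr_hosts
    with_seed(derive_seed(config$seed, 5L), {
      dirs <- switch(config$dmr_direction,
                     both = rep(c("hyper", "hypo"), length.out = n),
                     rep(config$dmr_direction, n))
      planted <- data.table::data.table(
        chrom = hosts$chrom, start = hosts$start, end = hosts$end,
        context = config$dmr_context, direction = dirs,
        effect = config$dmr_effect)
    })
    for (i in seq_len(nrow(planted))) {
      sgn <- if (planted$direction[i] == "hyper") 1 else -1
      truth_case[chrom == planted$chrom[i] & pos >= planted$start[i] &
                   pos <= planted$end[i] & context == planted$context[i],
                 ml := pmin(1, pmax(0, ml + sgn * planted$effect[i]))]
    }
    return(list(truth_case = truth_case, planted = planted))
  }
  part <- compartment_partition(sim$genes, sim$tes, config$chrom_lengths)
  elig <- part[[config$dmr_compartment]]
  if (is.null(elig) || length(elig) == 0L)
    stop("capacity error: no eligible '", config$dmr_compartment,
         "' region to host DMRs", call. = FALSE)
  buffer <- 500L  # keep planted DMRs from book-ending each other
  rows <- vector("list", n)
  with_seed(derive_seed(config$seed, 5L), {
    for (i in seq_len(n)) {
      len <- as.integer(round(stats::runif(1L, config$dmr_length_range[1],
                                           config$dmr_length_range[2])))
      wide <- elig[IRanges::width(elig) >= len]
      if (length(wide) == 0L)
        stop("capacity error: cannot place DMR ", i, " of ", len,
             " bp in '", config$dmr_compartment, "'", call. = FALSE)
      j <- sample.int(length(wide), 1L,
                      prob = as.numeric(IRanges::width(wide)))
      s0 <- GenomicRanges::start(wide)[j]
      e0 <- GenomicRanges::end(wide)[j]
      dstart <- s0 + sample.int(e0 - s0 - len + 2L, 1L) - 1L
      dend <- dstart + len - 1L
      dir <- switch(config$dmr_direction,
                    both = if (i %% 2L == 1L) "hyper" else "hypo",
                    config$dmr_direction)
      rows[[i]] <- data.table::data.table(
        chrom = as.character(GenomeInfoDb::seqnames(wide)[j]),
        start = dstart, end = dend, context = config$dmr_context,
        direction = dir, effect = config$dmr_effect)
      cut <- GenomicRanges::GRanges(
        as.character(GenomeInfoDb::seqnames(wide)[j]),
        IRanges::IRanges(max(1L, dstart - buffer), dend + buffer))
      elig <- GenomicRanges::setdiff(elig, cut, ignore.strand = TRUE)
    }
  })
  planted <- data.table::rbindlist(rows)
  for (i in seq_len(nrow(planted))) {
    sgn <- if (planted$direction[i] == "hyper") 1 else -1
    truth_case[chrom == planted$chrom[i] & pos >= planted$start[i] &
                 pos <= planted$end[i] & context == planted$context[i],
               ml := pmin(1, pmax(0, ml + sgn * planted$effect[i]))]
  }
  list(truth_case = truth_case, planted = planted)
}

#' Simulate bisulfite read counts for one sample
#'
#' Per-site coverage is Poisson with the configured mean; the methylated
#' read count is Binomial(coverage, ML * (1 - r) + r): a read reports
#' methylated when the cytosine is methylated or when an unmethylated
#' cytosine escapes conversion (rate r). The replicate seed is derived
#' deterministically from (seed, condition, replicate), so identical
#' arguments give identical reports.
#'
#' @param truth a `methylome_truth` table.
#' @param config the [simulation_config()].
#' @param condition 1 (control) or 2 (case).
#' @param replicate replicate number.
#' @return cytosine-record `data.table` (the 7-column report layout).
#' @export
simulate_counts <- function(truth, config, condition, replicate) {
  r <- config$nonconversion_rate
  with_seed(derive_seed(config$seed, 3L, condition, replicate), {
    n <- nrow(truth)
    cov <- stats::rpois(n, config$coverage_mean)
    p <- truth$ml * (1 - r) + r
    m <- stats::rbinom(n, cov, p)
    data.table::data.table(
      chrom = truth$chrom, pos = truth$pos, strand = truth$strand,
      count_meth = m, count_unmeth = cov - m,
      context = truth$context, trinucleotide = truth$trinucleotide)
  })
}

#' Simulate a gene expression table with DE labels
#'
#' Baseline FPKMs are log-normal; a configured fraction of genes is
#' nonexpressed (FPKM < 0.1 in both conditions) and a configured fraction
#' is differentially expressed with a fold change drawn from `fold_range`
#' (up or down with equal probability). With `coupling` enabled, genes
#' whose promoter overlaps a planted hypermethylated DMR are biased toward
#' repression (and hypomethylated promoters toward induction) with
#' probability `coupling_prob`, mimicking methylation-driven expression
#' change.
#'
#' @param sim output of [simulate_genome()].
#' @param config the [simulation_config()].
#' @param planted planted-DMR table (needed when coupling is enabled).
#' @param promoter_span promoter width used for coupling (default 2000).
#' @return `data.table` with `gene_id`, `fpkm_control`, `fpkm_case`,
#'   `de_label`.
#' @export
simulate_expression <- function(sim, config, planted = NULL,
                                promoter_span = 2000L) {
  em <- config$expression_model
  g <- sim$genes$genes
  ng <- nrow(g)
  with_seed(derive_seed(config$seed, 4L), {
    nonexpr <- stats::rbinom(ng, 1L, em$nonexpressed_fraction) == 1L
    base <- stats::rlnorm(ng, em$meanlog, em$sdlog)
    base[nonexpr] <- stats::runif(sum(nonexpr), 0, 0.099)
    lab <- rep("none", ng)
    eligible <- which(!nonexpr)
    n_de <- round(em$de_fraction * length(eligible))
    de_idx <- if (n_de > 0L) sample(eligible, n_de) else integer()
    lab[de_idx] <- sample(c("up", "down"), length(de_idx), replace = TRUE)

    if (isTRUE(em$coupling) && !is.null(planted) && nrow(planted)) {
      reg <- gene_region_table(sim$genes, promoter_span, promoter_span)
      prom <- reg[reg$region == "promoter"]
      hit <- GenomicRanges::findOverlaps(ranges_of(planted),
                                         ranges_of(prom))
      touched <- data.table::data.table(
        gene_id = prom$gene_id[S4Vectors::subjectHits(hit)],
        direction = planted$direction[S4Vectors::queryHits(hit)])
      for (i in seq_len(nrow(touched))) {
        gi <- match(touched$gene_id[i], g$gene_id)
        if (nonexpr[gi]) next
        if (stats::runif(1) < em$coupling_prob)
          lab[gi] <- if (touched$direction[i] == "hyper") "down" else "up"
      }
    }

    fold <- stats::runif(ng, em$fold_range[1], em$fold_range[2])
    fpkm_case <- base
    fpkm_case[lab == "up"] <- base[lab == "up"] * fold[lab == "up"]
    fpkm_case[lab == "down"] <- base[lab == "down"] / fold[lab == "down"]
    data.table::data.table(gene_id = g$gene_id,
                           fpkm_control = round(base, 4),
                           fpkm_case = round(fpkm_case, 4),
                           de_label = lab)[order(gene_id)]
  })
}

#' Run the full simulator
#'
#' Generates the annotated genome, condition-1 truth, planted DMRs
#' (condition 2), per-replicate bisulfite count reports for both
#' conditions, and the expression table. Everything is a deterministic
#' function of the configuration (including its seed).
#'
#' @param config a [simulation_config()].
#' @return object of class `methylome_simulation`: list with `genome`,
#'   `genes`, `tes`, `truth_control`, `truth_case`, `planted`, `counts`
#'   (nested list `counts$control[[rep]]`, `counts$case[[rep]]`),
#'   `expression`, `config`.
#' @export
simulate_methylome <- function(config) {
  sim <- simulate_genome(config)
  truth1 <- assign_true_methylation(sim, config)
  pl <- plant_dmrs(truth1, sim, config)
  reps <- config$replicates_per_condition
  counts <- list(
    control = lapply(seq_len(reps), function(rr)
      simulate_counts(truth1, config, condition = 1L, replicate = rr)),
    case = lapply(seq_len(reps), function(rr)
      simulate_counts(pl$truth_case, config, condition = 2L,
                      replicate = rr)))
  expression <- simulate_expression(sim, config, planted = pl$planted)
  structure(list(genome = sim$genome, genes = sim$genes, tes = sim$tes,
                 truth_control = truth1, truth_case = pl$truth_case,
                 planted = pl$planted, counts = counts,
                 expression = expression, config = config),
            class = "methylome_simulation")
}

#' @export
print.methylome_simulation <- function(x, ...) {
  cat("methylome_simulation:",
      format(sum(chrom_lengths(x$genome)), big.mark = ","), "bp genome |",
      nrow(x$genes$genes), "genes |", nrow(x$tes), "TEs |",
      nrow(x$planted), "planted DMRs |",
      length(x$counts$control), "replicates x 2 conditions\n")
  invisible(x)
}
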