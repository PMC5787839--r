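## Compartment tables, metagene and TE methylation profiles.

COMPARTMENTS <- c("te", "utr5", "cds", "utr3", "intron",
                  "promoter", "downstream", "intergenic")

#' Disjoint genomic compartment partition
#'
#' Splits every base of the genome into exactly one compartment with the
#' precedence TE > gene sub-feature (5'UTR, CDS, 3'UTR, intron) >
#' promoter/downstream flank > intergenic. Promoters are `promoter_span` bp
#' upstream of the transcript start (strand-aware); downstream regions
#' mirror them at the transcript end.
#'
#' @param genes a [gene_models()] object.
#' @param tes a [te_annotation()] table (may be empty).
#' @param chrom_len named chromosome lengths.
#' @param promoter_span,downstream_span flank sizes in bp (defaults 2000).
#' @return named list of disjoint `GRanges`, one per compartment.
#' @export
compartment_partition <- function(genes, tes, chrom_len,
                                  promoter_span = 2000L,
                                  downstream_span = 2000L) {
  gr <- function(dt) {
    if (is.null(dt) || nrow(dt) == 0L)
      return(GenomicRanges::GRanges())
    GenomicRanges::reduce(ranges_of(dt))
  }
  g <- genes$genes
  parts <- genes$parts
  plus <- g$strand == "+"
  prom <- data.table::data.table(
    chrom = g$chrom,
    start = ifelse(plus, pmax(1L, g$start - promoter_span), g$end + 1L),
    end = pmin(ifelse(plus, g$start - 1L, g$end + promoter_span),
               chrom_len[g$chrom]))
  down <- data.table::data.table(
    chrom = g$chrom,
    start = ifelse(plus, g$end + 1L, pmax(1L, g$start - downstream_span)),
    end = pmin(ifelse(plus, g$end + downstream_span, g$start - 1L),
               chrom_len[g$chrom]))
  pm <- merge(parts, g[, .(gene_id, chrom)], by = "gene_id")
  raw <- list(
    te = gr(tes),
    utr5 = gr(pm[type == "utr5", .(chrom, start, end)]),
    cds = gr(pm[type == "cds", .(chrom, start, end)]),
    utr3 = gr(pm[type == "utr3", .(chrom, start, end)]),
    gene_body = gr(g[, .(chrom, start, end)]),
    promoter = gr(prom[end >= start]),
    downstream = gr(down[end >= start])
  )
  genome_gr <- GenomicRanges::GRanges(
    names(chrom_len), IRanges::IRanges(1L, unname(chrom_len)))
  taken <- GenomicRanges::GRanges()
  out <- list()
  claim <- function(x) {
    x <- GenomicRanges::setdiff(x, taken, ignore.strand = TRUE)
    taken <<- GenomicRanges::reduce(c(taken, x))
    x
  }
  out$te <- claim(raw$te)
  out$utr5 <- claim(raw$utr5)
  out$cds <- claim(raw$cds)
  out$utr3 <- claim(raw$utr3)
  out$intron <- claim(raw$gene_body)  # gene bases not in any exon part
  out$promoter <- claim(raw$promoter)
  out$downstream <- claim(raw$downstream)
  out$intergenic <- GenomicRanges::setdiff(genome_gr, taken,
                                           ignore.strand = TRUE)
  out
}

## Map site positions to compartment labels (exactly one per site).
site_compartments <- function(sites, partition) {
  gr <- site_ranges(sites)
  lab <- rep(NA_character_, nrow(sites))
  for (comp in names(partition)) {
    hit <- GenomicRanges::findOverlaps(gr, partition[[comp]])
    lab[S4Vectors::queryHits(hit)] <- comp
  }
  lab
}

#' Per-compartment methylation table
#'
#' Count-pooled methylation level per genomic compartment and context, with
#' the disjoint precedence of [compartment_partition()]. Compartments with
#' no covered sites of a context are reported with `ml = NA` (flagged
#' missing, not zero). An `exon` row (5'UTR + CDS + 3'UTR pooled) is
#' appended for convenience.
#'
#' @param sm `site_methylation` table.
#' @param genes,tes annotations.
#' @param chrom_len named chromosome lengths.
#' @param promoter_span,downstream_span flank sizes in bp.
#' @param exclude_chroms chromosomes to ignore (e.g. the spike-in).
#' @return `data.table` with `compartment`, `context`, `meth`, `unmeth`,
#'   `n_sites`, `ml`.
#' @export
compartment_methylation <- function(sm, genes, tes, chrom_len,
                                    promoter_span = 2000L,
                                    downstream_span = 2000L,
                                    exclude_chroms = character()) {
  part <- compartment_partition(genes, tes, chrom_len,
                                promoter_span, downstream_span)
  dt <- data.table::as.data.table(sm)[covered == TRUE &
                                        !chrom %in% exclude_chroms]
  dt[, compartment := site_compartments(dt, part)]
  agg <- dt[, .(meth = sum(count_meth), unmeth = sum(count_unmeth),
                n_sites = .N), by = .(compartment, context)]
  grid <- data.table::CJ(compartment = c(COMPARTMENTS, "exon"),
                         context = CONTEXTS)
  exon <- agg[compartment %in% c("utr5", "cds", "utr3"),
              .(meth = sum(meth), unmeth = sum(unmeth),
                n_sites = sum(n_sites), compartment = "exon"),
              by = context]
  agg <- rbind(agg, exon[, .(compartment, context, meth, unmeth, n_sites)])
  out <- merge(grid, agg, by = c("compartment", "context"), all.x = TRUE)
  out[is.na(n_sites), `:=`(meth = 0, unmeth = 0, n_sites = 0L)]
  out[, ml := pooled_ml(meth, unmeth)]
  out[order(factor(compartment, levels = c(COMPARTMENTS, "exon")),
            factor(context, levels = CONTEXTS))]
}

## Shared engine: pool covered-site counts onto a fixed bin axis over
## per-feature segments. `segments` is a data.table with one row per
## (feature, segment): feature_id, chrom, strand, seg (label), start, end,
## plus the bins-per-segment config `bins` (named integer vector in 5'->3'
## segment order). Sites are assigned proportionally within their segment,
## flipped for minus-strand features.
profile_engine <- function(sm, segments, bins) {
  dt <- data.table::as.data.table(sm)[covered == TRUE]
  seg <- data.table::as.data.table(segments)[end >= start]
  hit <- GenomicRanges::findOverlaps(site_ranges(dt), ranges_of(seg))
  qi <- S4Vectors::queryHits(hit); si <- S4Vectors::subjectHits(hit)
  dd <- data.table::data.table(
    pos = dt$pos[qi], context = dt$context[qi],
    m = dt$count_meth[qi], u = dt$count_unmeth[qi],
    seg = seg$seg[si], sstart = seg$start[si], send = seg$end[si],
    strand = seg$strand[si])
  offsets <- c(0L, cumsum(unname(bins)))[seq_along(bins)]
  names(offsets) <- names(bins)
  nb <- bins[dd$seg]
  len <- dd$send - dd$sstart + 1L
  rel <- ifelse(dd$strand == "+",
                dd$pos - dd$sstart, dd$send - dd$pos)
  local_bin <- pmin(nb - 1L, floor(rel / len * nb)) + 1L
  dd[, bin := offsets[seg] + local_bin]
  agg <- dd[, .(meth = sum(m), unmeth = sum(u), n_sites = .N),
            by = .(bin, context)]
  grid <- data.table::CJ(bin = seq_len(sum(bins)), context = CONTEXTS)
  out <- merge(grid, agg, by = c("bin", "context"), all.x = TRUE)
  out[is.na(n_sites), `:=`(meth = 0, unmeth = 0, n_sites = 0L)]
  out[, ml := pooled_ml(meth, unmeth)]
  bin2seg <- rep(names(bins), bins)
  out[, segment := bin2seg[bin]]
  data.table::setorder(out, bin, context)
  data.table::setattr(out, "bins", bins)
  out[, .(bin, segment, context, meth, unmeth, n_sites, ml)]
}

## Per-gene segment table in transcript orientation:
## promoter | utr5 | body | utr3 | downstream.
gene_segments <- function(genes, flank = 2000L) {
  g <- genes$genes
  p <- genes$parts
  u5 <- p[type == "utr5", .(u5s = min(start), u5e = max(end)), by = gene_id]
  u3 <- p[type == "utr3", .(u3s = min(start), u3e = max(end)), by = gene_id]
  g2 <- merge(merge(g, u5, by = "gene_id", all.x = TRUE),
              u3, by = "gene_id", all.x = TRUE)
  plus <- g2$strand == "+"
  ## genomic extents of the transcript-oriented segments
  seg_rows <- function(label, s, e) data.table::data.table(
    feature_id = g2$gene_id, chrom = g2$chrom, strand = g2$strand,
    seg = label, start = as.integer(s), end = as.integer(e))
  ## 5' flank / 3' flank in genomic coords
  prom <- seg_rows("promoter",
                   ifelse(plus, g2$start - flank, g2$end + 1L),
                   ifelse(plus, g2$start - 1L, g2$end + flank))
  down <- seg_rows("downstream",
                   ifelse(plus, g2$end + 1L, g2$start - flank),
                   ifelse(plus, g2$end + flank, g2$start - 1L))
  ## UTR extents (may be absent -> empty segment)
  utr5 <- seg_rows("utr5",
                   data.table::fifelse(is.na(g2$u5s), 0L,
                                       as.integer(g2$u5s)),
                   data.table::fifelse(is.na(g2$u5e), -1L,
                                       as.integer(g2$u5e)))
  utr3 <- seg_rows("utr3",
                   data.table::fifelse(is.na(g2$u3s), 0L,
                                       as.integer(g2$u3s)),
                   data.table::fifelse(is.na(g2$u3e), -1L,
                                       as.integer(g2$u3e)))
  ## body = transcript span minus the UTR extents (strand-aware)
  bstart <- ifelse(plus,
                   ifelse(is.na(g2$u5e), g2$start, g2$u5e + 1L),
                   ifelse(is.na(g2$u3e), g2$start, g2$u3e + 1L))
  bend <- ifelse(plus,
                 ifelse(is.na(g2$u3s), g2$end, g2$u3s - 1L),
                 ifelse(is.na(g2$u5s), g2$end, g2$u5s - 1L))
  body <- seg_rows("body", bstart, bend)
  rbind(prom, utr5, body, utr3, down)
}

#' Metagene methylation profile
#'
#' Every gene is rescaled to a fixed bin axis -- promoter flank, 5'UTR,
#' gene body, 3'UTR, downstream flank -- and covered-site read counts are
#' pooled per bin and context across genes (count-pooled level per bin).
#' Minus-strand genes are flipped so the axis always runs 5' to 3'.
#' Genes shorter than the bin count are assigned proportionally.
#'
#' @param sm `site_methylation` table.
#' @param genes a [gene_models()] object (optionally a subset of genes via
#'   `gene_ids`).
#' @param flank flank width in bp (default 2000).
#' @param bins named integer vector of bins per segment, in axis order.
#' @param gene_ids optional subset of genes to profile.
#' @return `data.table` (class-compatible with [te_profile()]) with `bin`,
#'   `segment`, `context`, `meth`, `unmeth`, `n_sites`, `ml`; bin counts are
#'   stored in the `"bins"` attribute.
#' @export
metagene_profile <- function(sm, genes, flank = 2000L,
                             bins = c(promoter = 20L, utr5 = 5L,
                                      body = 20L, utr3 = 5L,
                                      downstream = 20L),
                             gene_ids = NULL) {
  stopifnot(inherits(genes, "gene_models"))
  if (!is.null(gene_ids)) {
    genes <- gene_models(genes$genes[gene_id %in% gene_ids],
                         genes$parts[gene_id %in% gene_ids])
  }
  if (nrow(genes$genes) == 0L) stop("no features", call. = FALSE)
  profile_engine(sm, gene_segments(genes, flank), bins)
}

#' Transposable-element methylation profile
#'
#' As [metagene_profile()] with a single body segment: upstream flank,
#' TE body, downstream flank.
#'
#' @param sm `site_methylation` table.
#' @param tes a [te_annotation()] table.
#' @param flank flank width in bp (default 2000).
#' @param body_bins,flank_bins bins for the body and each flank.
#' @return profile `data.table`; see [metagene_profile()].
#' @export
te_profile <- function(sm, tes, flank = 2000L, body_bins = 20L,
                       flank_bins = 20L) {
  if (is.null(tes) || nrow(tes) == 0L) stop("no features", call. = FALSE)
  plus <- tes$strand == "+"
  seg_rows <- function(label, s, e) data.table::data.table(
    feature_id = tes$te_id, chrom = tes$chrom, strand = tes$strand,
    seg = label, start = as.integer(s), end = as.integer(e))
  up <- seg_rows("upstream",
                 ifelse(plus, tes$start - flank, tes$end + 1L),
                 ifelse(plus, tes$start - 1L, tes$end + flank))
  body <- seg_rows("body", tes$start, tes$end)
  down <- seg_rows("downstream",
                   ifelse(plus, tes$end + 1L, tes$start - flank),
                   ifelse(plus, tes$end + flank, tes$start - 1L))
  profile_engine(sm, rbind(up, body, down),
                 c(upstream = flank_bins, body = body_bins,
                   downstream = flank_bins))
}

#' One metagene profile per gene group
#'
#' @param sm `site_methylation` table.
#' @param genes a [gene_models()] object.
#' @param grouping `data.table` with `id` (gene id) and `group`, e.g. from
#'   [quintile_partition()]. Empty groups are omitted with a warning.
#' @param ... passed to [metagene_profile()].
#' @return named list of profile tables, one per group, on a shared axis.
#' @export
profile_by_group <- function(sm, genes, grouping, ...) {
  grouping <- data.table::as.data.table(grouping)
  out <- list()
  for (grp in unique(grouping$group)) {
    ids <- grouping[group == grp]$id
    ids <- intersect(ids, genes$genes$gene_id)
    if (length(ids) == 0L) {
      warning("group '", grp, "' has no genes; omitted", call. = FALSE)
      next
    }
    out[[as.character(grp)]] <- metagene_profile(sm, genes,
                                                 gene_ids = ids, ...)
  }
  out
}

#' TE methylation by class and length quintile
#'
#' Within each TE class with at least `min_class_size` members, TEs are
#' split into length quintiles (1st = shortest) and covered-site counts are
#' pooled per quintile and context.
#'
#' @param tes a [te_annotation()] table.
#' @param sm `site_methylation` table.
#' @param min_class_size classes smaller than this are skipped (default 5).
#' @return `data.table` with `te_class`, `group`, `context`, `meth`,
#'   `unmeth`, `n_sites`, `ml`, `n_tes`, `mean_length`.
#' @export
te_length_quintiles <- function(tes, sm, min_class_size = 5L) {
  dt <- data.table::as.data.table(sm)[covered == TRUE]
  out <- list()
  for (cls in sort(unique(tes$te_class))) {
    sub <- tes[te_class == cls]
    if (nrow(sub) < min_class_size) {
      message("TE class '", cls, "' has fewer than ", min_class_size,
              " members; skipped")
      next
    }
    qa <- quintile_partition(sub$end - sub$start + 1L, sub$te_id)
    sub <- merge(sub, qa, by.x = "te_id", by.y = "id")
    hit <- GenomicRanges::findOverlaps(site_ranges(dt), ranges_of(sub))
    dd <- data.table::data.table(
      group = sub$group[S4Vectors::subjectHits(hit)],
      context = dt$context[S4Vectors::queryHits(hit)],
      m = dt$count_meth[S4Vectors::queryHits(hit)],
      u = dt$count_unmeth[S4Vectors::queryHits(hit)])
    agg <- dd[, .(meth = sum(m), unmeth = sum(u), n_sites = .N),
              by = .(group, context)]
    meta <- sub[, .(n_tes = .N,
                    mean_length = mean(end - start + 1)), by = group]
    agg <- merge(agg, meta, by = "group")
    agg[, `:=`(te_class = cls, ml = pooled_ml(meth, unmeth))]
    out[[cls]] <- agg
  }
  if (length(out) == 0L)
    stop("no TE class large enough for quintiles", call. = FALSE)
  res <- data.table::rbindlist(out)
  data.table::setcolorder(res, c("te_class", "group", "context"))
  data.table::setorder(res, te_class, group, context)
  res[]
}
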