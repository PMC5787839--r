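## Gene models and transposable-element annotations.
## All internal coordinates are 1-based inclusive (GFF3 convention).

TE_CLASSES <- c("LTR_Gypsy", "LTR_Copia", "hAT_Tag1", "hAT_Tip100", "other")
GENE_PART_TYPES <- c("exon", "cds", "utr5", "utr3")

#' Gene model container
#'
#' Holds gene spans plus sub-feature intervals (exons, CDS, UTRs). Introns
#' are implied (gene span minus exons). Invariants checked: parts lie within
#' their gene span; exons are non-overlapping; the 5'UTR/CDS/3'UTR parts
#' partition the exons (same bases, no overlap).
#'
#' @param genes `data.frame` with `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (1-based inclusive transcript span).
#' @param parts `data.frame` with `gene_id`, `type` (one of
#'   `exon`, `cds`, `utr5`, `utr3`), `start`, `end`.
#' @return object of class `gene_models` (list of the two validated tables).
#' @export
gene_models <- function(genes, parts) {
  genes <- data.table::as.data.table(genes)
  parts <- data.table::as.data.table(parts)
  stopifnot(all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)),
            all(c("gene_id", "type", "start", "end") %in% names(parts)))
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be + or -", call. = FALSE)
  if (any(genes$end < genes$start) || any(parts$end < parts$start))
    stop("interval end < start", call. = FALSE)
  if (!all(parts$type %in% GENE_PART_TYPES))
    stop("unknown part type (expected exon/cds/utr5/utr3)", call. = FALSE)
  if (!all(parts$gene_id %in% genes$gene_id))
    stop("part references unknown gene_id", call. = FALSE)

  ## parts inside their gene span
  m <- merge(parts, genes[, .(gene_id, gstart = start, gend = end)],
             by = "gene_id")
  bad <- m$start < m$gstart | m$end > m$gend
  if (any(bad))
    stop("feature outside parent gene span for gene ",
         m$gene_id[which(bad)[1L]], call. = FALSE)

  ## exons non-overlapping within each gene; UTR/CDS partition exons.
  ## Interval algebra done per gene by abusing gene_id as a seqname.
  gr_of <- function(x) GenomicRanges::GRanges(
    x$gene_id, IRanges::IRanges(x$start, x$end))
  ex <- parts[type == "exon"]
  if (nrow(ex)) {
    gre <- gr_of(ex)
    red <- GenomicRanges::reduce(gre, min.gapwidth = 0L)
    if (sum(IRanges::width(red)) != sum(IRanges::width(gre)))
      stop("overlapping exons within a gene", call. = FALSE)
    sub <- parts[type %in% c("cds", "utr5", "utr3")]
    if (nrow(sub)) {
      grs <- gr_of(sub)
      reds <- GenomicRanges::reduce(grs, min.gapwidth = 0L)
      if (sum(IRanges::width(reds)) != sum(IRanges::width(grs)))
        stop("overlapping UTR/CDS parts within a gene", call. = FALSE)
      outside <- GenomicRanges::setdiff(grs, gre)
      if (sum(IRanges::width(outside)) > 0)
        stop("UTR/CDS bases outside exons", call. = FALSE)
      uncovered <- GenomicRanges::setdiff(gre, grs)
      if (sum(IRanges::width(uncovered)) > 0)
        stop("exon bases not covered by UTR/CDS partition", call. = FALSE)
    }
  }
  data.table::setkey(genes, gene_id)
  data.table::setorder(parts, gene_id, start)
  structure(list(genes = genes[], parts = parts[]), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,", nrow(x$parts),
      "sub-features on", length(unique(x$genes$chrom)), "chromosome(s)\n")
  invisible(x)
}

#' Transposable-element annotation table
#'
#' @param tes `data.frame` with `te_id`, `chrom`, `strand`, `start`, `end`,
#'   `te_class`. Classes outside `class_set` are mapped to `"other"` with a
#'   warning (RepeatMasker vocabularies vary).
#' @param class_set allowed TE classes.
#' @return validated `data.table` of class `te_annotation`.
#' @export
te_annotation <- function(tes, class_set = TE_CLASSES) {
  tes <- data.table::as.data.table(tes)
  stopifnot(all(c("te_id", "chrom", "strand", "start", "end", "te_class")
                %in% names(tes)))
  if (any(tes$end < tes$start)) stop("TE end < start", call. = FALSE)
  if (anyDuplicated(tes$te_id)) stop("duplicate te_id", call. = FALSE)
  unknown <- !tes$te_class %in% class_set
  if (any(unknown)) {
    warning(sum(unknown), " TE(s) with unrecognized class mapped to 'other'",
            call. = FALSE)
    tes[unknown, te_class := "other"]
  }
  data.table::setorder(tes, chrom, start)
  data.table::setattr(tes, "class", c("te_annotation", class(tes)))
  tes[]
}

#' Read gene or TE annotations
#'
#' Genes are read from GFF3 (`type` gene with exon/CDS/UTR children linked by
#' `Parent`, optionally through an mRNA level); TEs from BED6(+1), where the
#' optional seventh column carries the TE class, or from GFF3 with a
#' `te_class` attribute. BED input is converted from 0-based half-open to the
#' internal 1-based inclusive convention on read.
#'
#' @param path annotation file (`.gff3`/`.gff` or `.bed`).
#' @param kind `"gene"` or `"te"`.
#' @return a [gene_models()] object or a [te_annotation()] table.
#' @export
read_annotations <- function(path, kind = c("gene", "te")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (kind == "gene") {
    if (!ext %in% c("gff", "gff3"))
      stop("gene annotations must be GFF3", call. = FALSE)
    gr <- rtracklayer::import(path, format = "gff3")
    df <- data.table::data.table(
      chrom = as.character(GenomeInfoDb::seqnames(gr)),
      start = GenomicRanges::start(gr),
      end = GenomicRanges::end(gr),
      strand = as.character(GenomicRanges::strand(gr)),
      type = as.character(gr$type),
      id = as.character(gr$ID %||% NA_character_),
      parent = vapply(as.list(gr$Parent %||% rep(list(character()), length(gr))),
                      function(p) if (length(p)) p[[1L]] else NA_character_,
                      character(1))
    )
    genes <- df[type == "gene",
                .(gene_id = id, chrom, strand, start, end)]
    if (nrow(genes) == 0L) stop("no gene records in ", path, call. = FALSE)
    ## resolve transcript-level parents to genes
    tx2gene <- df[type %in% c("mRNA", "transcript") & !is.na(parent),
                  stats::setNames(parent, id)]
    type_map <- c(exon = "exon", CDS = "cds",
                  five_prime_UTR = "utr5", three_prime_UTR = "utr3")
    kids <- df[type %in% names(type_map)]
    kids[, gene_id := data.table::fifelse(parent %in% names(tx2gene),
                                          tx2gene[parent], parent)]
    parts <- kids[, .(gene_id, type = type_map[type], start, end)]
    gene_models(genes, parts)
  } else {
    if (ext == "bed") {
      dt <- read_bed(path)
      cls <- if (ncol(dt) >= 7L) as.character(dt[[7L]]) else "other"
      te_annotation(data.table::data.table(
        te_id = if ("name" %in% names(dt)) dt$name
                else sprintf("te%06d", seq_len(nrow(dt))),
        chrom = dt$chrom,
        strand = if ("strand" %in% names(dt)) dt$strand else "+",
        start = dt$start, end = dt$end, te_class = cls))
    } else if (ext %in% c("gff", "gff3")) {
      gr <- rtracklayer::import(path, format = "gff3")
      te_annotation(data.table::data.table(
        te_id = as.character(gr$ID %||% sprintf("te%06d", seq_along(gr))),
        chrom = as.character(GenomeInfoDb::seqnames(gr)),
        strand = as.character(GenomicRanges::strand(gr)),
        start = GenomicRanges::start(gr),
        end = GenomicRanges::end(gr),
        te_class = as.character(gr$te_class %||% "other")))
    } else stop("unrecognized annotation format: .", ext, call. = FALSE)
  }
}

#' Write gene models to GFF3
#' @param models a [gene_models()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_gff3 <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  p <- merge(models$parts, g[, .(gene_id, chrom, strand)], by = "gene_id")
  type_map <- c(exon = "exon", cds = "CDS",
                utr5 = "five_prime_UTR", utr3 = "three_prime_UTR")
  rows <- rbind(
    data.table::data.table(chrom = g$chrom, start = g$start, end = g$end,
                           strand = g$strand, type = "gene",
                           ID = g$gene_id, Parent = NA_character_),
    data.table::data.table(chrom = p$chrom, start = p$start, end = p$end,
                           strand = p$strand, type = type_map[p$type],
                           ID = NA_character_, Parent = p$gene_id)
  )
  rows <- rows[order(factor(chrom, levels = unique(g$chrom)), start,
                     factor(type, levels = c("gene", "exon", "CDS",
                                             "five_prime_UTR",
                                             "three_prime_UTR")))]
  gr <- GenomicRanges::GRanges(rows$chrom,
                               IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  gr$type <- rows$type
  gr$phase <- ifelse(rows$type == "CDS", 0L, NA_integer_)
  gr$ID <- rows$ID
  gr$Parent <- ifelse(is.na(rows$Parent), "", rows$Parent)
  gr$Parent <- S4Vectors::unname(
    IRanges::CharacterList(lapply(gr$Parent,
                                  function(x) if (nzchar(x)) x else character())))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write TE annotations as BED6+1
#'
#' The seventh column carries the TE class; coordinates become 0-based
#' half-open on write.
#'
#' @param tes a [te_annotation()] table.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_te_bed <- function(tes, path) {
  write_bed(data.table::data.table(
    chrom = tes$chrom, start = tes$start, end = tes$end,
    name = tes$te_id, score = 0L, strand = tes$strand,
    te_class = tes$te_class), path, extra_cols = "te_class")
}
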