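## Bismark-style cytosine reports, expression tables and BED intervals.
## Internal coordinates are 1-based inclusive throughout; BED is converted
## (0-based half-open) only at the I/O boundary.

REPORT_COLS <- c("chrom", "pos", "strand", "count_meth", "count_unmeth",
                 "context", "trinucleotide")

## Context implied by the two bases downstream of the cytosine.
context_from_downstream <- function(b1, b2) {
  data.table::fcase(
    b1 == "G", "CG",
    b2 == "G", "CHG",
    b1 %in% c("A", "C", "T") & b2 %in% c("A", "C", "T"), "CHH",
    default = NA_character_
  )
}

validate_report <- function(dt, where = "cytosine report") {
  if (nrow(dt) == 0L) return(invisible(dt))
  fail <- function(mask, msg) {
    if (any(mask)) {
      stop(where, " line ", which(mask)[1L], ": ", msg, call. = FALSE)
    }
  }
  fail(!dt$strand %in% c("+", "-"), "strand must be + or -")
  fail(is.na(dt$pos) | dt$pos < 1L, "position must be a positive integer")
  fail(is.na(dt$count_meth) | dt$count_meth < 0L |
         is.na(dt$count_unmeth) | dt$count_unmeth < 0L,
       "read counts must be non-negative integers")
  fail(!dt$context %in% CONTEXTS, "context must be CG, CHG or CHH")
  fail(nchar(dt$trinucleotide) != 3L | substr(dt$trinucleotide, 1, 1) != "C",
       "trinucleotide must be a 3-mer starting with C")
  implied <- context_from_downstream(substr(dt$trinucleotide, 2, 2),
                                     substr(dt$trinucleotide, 3, 3))
  fail(is.na(implied) | implied != dt$context,
       "context is inconsistent with trinucleotide")
  invisible(dt)
}

empty_report <- function() {
  data.table::data.table(
    chrom = character(), pos = integer(), strand = character(),
    count_meth = integer(), count_unmeth = integer(),
    context = character(), trinucleotide = character()
  )
}

#' Read a Bismark-style cytosine report
#'
#' Seven tab-separated columns without header: chrom, 1-based position,
#' strand, methylated read count, unmethylated read count, context
#' (CG/CHG/CHH), trinucleotide on the cytosine's strand. Records are
#' validated (counts non-negative, context consistent with the
#' trinucleotide); the first offending line is reported.
#'
#' @param path TSV file.
#' @return a `data.table` with columns `chrom, pos, strand, count_meth,
#'   count_unmeth, context, trinucleotide`; empty (with the same columns)
#'   for an empty file. Input order is preserved.
#' @export
read_cytosine_report <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) return(empty_report())
  dt <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = REPORT_COLS,
                          colClasses = list(character = c(1, 3, 6, 7),
                                            integer = c(2, 4, 5)))
  if (ncol(dt) != 7L)
    stop("cytosine report must have 7 tab-separated columns", call. = FALSE)
  validate_report(dt, where = basename(path))
  dt[]
}

#' Write a Bismark-style cytosine report
#'
#' Records are written in deterministic order: chromosomes in the order
#' given by `chrom_order` (or first appearance), then position, then strand.
#'
#' @param records cytosine record `data.table` (see [read_cytosine_report()]).
#' @param path output file.
#' @param chrom_order optional chromosome ordering.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(records, path, chrom_order = NULL) {
  records <- data.table::as.data.table(records)[, REPORT_COLS, with = FALSE]
  validate_report(records, where = "records")
  lv <- chrom_order %||% unique(records$chrom)
  records <- records[order(factor(chrom, levels = lv), pos, strand)]
  data.table::fwrite(records, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a gene expression table
#'
#' Tab-separated with header. Requires columns `gene_id` and `fpkm`
#' (or `fpkm_control`/`fpkm_case` pairs as written by the simulator);
#' optional `de_label` in up/down/none.
#'
#' @param path TSV file.
#' @return `data.table` with `gene_id`, `fpkm` (and/or `fpkm_control`,
#'   `fpkm_case`), optional `de_label`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (!"gene_id" %in% names(dt))
    stop("expression table needs a gene_id column", call. = FALSE)
  fcols <- intersect(c("fpkm", "fpkm_control", "fpkm_case"), names(dt))
  if (length(fcols) == 0L)
    stop("expression table needs an fpkm column", call. = FALSE)
  for (cc in fcols) {
    if (any(is.na(dt[[cc]]) | dt[[cc]] < 0))
      stop("negative or missing FPKM in column ", cc, call. = FALSE)
  }
  if ("de_label" %in% names(dt) &&
      !all(dt$de_label %in% c("up", "down", "none")))
    stop("de_label must be up, down or none", call. = FALSE)
  dt[]
}

#' Write an expression table
#' @param expression `data.table` with `gene_id` plus FPKM column(s) and an
#'   optional `de_label`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(expression, path) {
  data.table::fwrite(data.table::as.data.table(expression), path, sep = "\t")
  invisible(path)
}

#' Write intervals as BED
#'
#' Internal 1-based inclusive intervals are converted to BED 0-based
#' half-open on write. Columns beyond BED6 (`name`, `score`, `strand`
#' defaulted when absent) are appended as BED6+ extra fields.
#'
#' @param intervals `data.frame` with `chrom`, `start`, `end` (1-based
#'   inclusive) and optionally `name`, `score`, `strand` plus extra columns.
#' @param path output file.
#' @param extra_cols character vector of extra column names to append after
#'   the six BED fields.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path, extra_cols = character()) {
  dt <- data.table::as.data.table(intervals)
  if (any(dt$end < dt$start)) stop("end < start in intervals", call. = FALSE)
  out <- data.table::data.table(
    chrom = dt$chrom,
    start = dt$start - 1L,
    end = dt$end,
    name = if ("name" %in% names(dt)) dt$name else ".",
    score = if ("score" %in% names(dt)) dt$score else 0,
    strand = if ("strand" %in% names(dt)) dt$strand else "."
  )
  for (cc in extra_cols) out[[cc]] <- dt[[cc]]
  out <- out[order(factor(chrom, levels = unique(chrom)), start)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a BED file as 1-based inclusive intervals
#'
#' @param path BED file (at least 3 columns; 6+ recognized).
#' @return `data.table` with `chrom`, `start`, `end` (1-based inclusive) and,
#'   when present, `name`, `score`, `strand` and any extra columns.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  dt <- data.table::fread(path, sep = "\t", header = FALSE)
  if (ncol(dt) < 3L) stop("BED needs at least 3 columns", call. = FALSE)
  base <- c("chrom", "start", "end", "name", "score", "strand")
  names(dt)[seq_len(min(ncol(dt), 6L))] <- base[seq_len(min(ncol(dt), 6L))]
  dt[, start := start + 1L]  # 0-based half-open -> 1-based inclusive
  if (any(dt$end < dt$start))
    stop("invalid BED interval (end < start after conversion)", call. = FALSE)
  dt[]
}
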