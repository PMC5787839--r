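#' Genome sequence container
#'
#' Wraps a [Biostrings::DNAStringSet] of chromosome sequences together with an
#' optional spike-in chromosome flag. The spike-in chromosome (typically the
#' lambda phage genome added as an unmethylated control before bisulfite
#' treatment) is used to estimate the nonconversion rate.
#'
#' @param seqs named character vector or `DNAStringSet` of chromosome
#'   sequences over the alphabet A, C, G, T, N (lower case accepted,
#'   normalized to upper case).
#' @param spike_in_chrom optional name of the unmethylated control chromosome;
#'   must be one of the chromosome names.
#' @return an object of class `genome_sequence` with elements `seq`
#'   (a `DNAStringSet`) and `spike_in_chrom`.
#' @export
genome_sequence <- function(seqs, spike_in_chrom = NULL) {
  if (is.character(seqs)) {
    seqs <- toupper(seqs)
    bad <- grepl("[^ACGTN]", seqs)
    if (any(bad))
      stop("non-ACGTN character in chromosome ",
           paste(names(seqs)[bad] %||% which(bad), collapse = ", "),
           call. = FALSE)
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  if (!methods::is(seqs, "DNAStringSet"))
    stop("seqs must be a character vector or DNAStringSet", call. = FALSE)
  nm <- names(seqs)
  if (is.null(nm) || any(nm == ""))
    stop("all chromosomes must be named", call. = FALSE)
  if (anyDuplicated(nm))
    stop("duplicate chromosome name: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  if (any(Biostrings::width(seqs) == 0L))
    stop("zero-length chromosome: ",
         paste(nm[Biostrings::width(seqs) == 0L], collapse = ", "),
         call. = FALSE)
  freq <- Biostrings::alphabetFrequency(seqs)
  bad <- rowSums(freq[, setdiff(colnames(freq), c("A", "C", "G", "T", "N")),
                      drop = FALSE]) > 0
  if (any(bad))
    stop("non-ACGTN character in chromosome ",
         paste(nm[bad], collapse = ", "), call. = FALSE)
  if (!is.null(spike_in_chrom) && !spike_in_chrom %in% nm)
    stop("spike_in_chrom '", spike_in_chrom,
         "' is not a chromosome name", call. = FALSE)
  structure(list(seq = seqs, spike_in_chrom = spike_in_chrom),
            class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("genome_sequence:", length(x$seq), "chromosome(s),",
      format(sum(Biostrings::width(x$seq)), big.mark = ","), "bp total\n")
  if (!is.null(x$spike_in_chrom))
    cat("  spike-in (unmethylated control):", x$spike_in_chrom, "\n")
  invisible(x)
}

#' Chromosome names and lengths of a genome
#' @param genome a [genome_sequence()] object.
#' @return named integer vector of chromosome lengths, in genome order.
#' @export
chrom_lengths <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  stats::setNames(Biostrings::width(genome$seq), names(genome$seq))
}

#' Read a genome from FASTA
#'
#' Sequences are uppercased; duplicate headers and characters outside
#' A/C/G/T/N are rejected.
#'
#' @param path FASTA file.
#' @param spike_in_chrom optional name of the unmethylated spike-in
#'   chromosome (e.g. `"lambda"`).
#' @return a [genome_sequence()] object.
#' @export
read_fasta <- function(path, spike_in_chrom = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  seqs <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ## keep only the first whitespace-delimited token of each header
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  genome_sequence(as.character(seqs), spike_in_chrom = spike_in_chrom)
}

#' Write a genome to FASTA
#' @param genome a [genome_sequence()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "genome_sequence"))
  Biostrings::writeXStringSet(genome$seq, filepath = path, width = 70L)
  invisible(path)
}
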