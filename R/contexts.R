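#' Classify cytosine contexts on both strands of a genome
#'
#' Every cytosine on the plus strand, and every guanine on the plus strand
#' (a cytosine when read on the minus strand), is classified into CG, CHG or
#' CHH (H = A, T or C) from the two bases immediately downstream on the
#' site's own strand. Sites whose two downstream bases run off the
#' chromosome end, or whose trinucleotide contains N, are excluded.
#'
#' @param genome a [genome_sequence()] object.
#' @return `data.table` with `chrom`, `pos` (1-based, always on the plus
#'   strand coordinate system), `strand`, `context`, `trinucleotide`
#'   (reported 5'->3' on the site's strand), sorted by chromosome (genome
#'   order), position, strand.
#' @export
classify_contexts <- function(genome) {
  stopifnot(inherits(genome, "genome_sequence"))
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  per_chrom <- lapply(names(genome$seq), function(cn) {
    ch <- strsplit(as.character(genome$seq[[cn]]), "", fixed = TRUE)[[1L]]
    L <- length(ch)

    ## plus strand: C at i, downstream bases at i+1, i+2
    i <- which(ch == "C")
    i <- i[i <= L - 2L]
    b1 <- ch[i + 1L]; b2 <- ch[i + 2L]
    keep <- b1 != "N" & b2 != "N"
    i <- i[keep]; b1 <- b1[keep]; b2 <- b2[keep]
    plus <- data.table::data.table(
      chrom = cn, pos = i, strand = "+",
      context = context_from_downstream(b1, b2),
      trinucleotide = paste0("C", b1, b2))

    ## minus strand: G at j reads as C; downstream (5'->3' on minus)
    ## are the complements of the bases at j-1, j-2
    j <- which(ch == "G")
    j <- j[j >= 3L]
    c1 <- unname(comp[ch[j - 1L]]); c2 <- unname(comp[ch[j - 2L]])
    keep <- c1 != "N" & c2 != "N"
    j <- j[keep]; c1 <- c1[keep]; c2 <- c2[keep]
    minus <- data.table::data.table(
      chrom = cn, pos = j, strand = "-",
      context = context_from_downstream(c1, c2),
      trinucleotide = paste0("C", c1, c2))

    rbind(plus, minus)
  })
  sites <- data.table::rbindlist(per_chrom)
  sites <- sites[order(factor(chrom, levels = names(genome$seq)), pos, strand)]
  sites[]
}
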