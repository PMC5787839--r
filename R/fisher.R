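## Two-sided Fisher exact test and FDR adjustment.

fisher_p_one <- function(a, b, c, d) {
  N <- a + b + c + d
  if (N == 0) {
    warning("all-zero contingency table; p = 1", call. = FALSE)
    return(1)
  }
  k <- a + b   # row-1 margin (draws)
  m <- a + c   # column-1 margin ("white balls")
  n <- b + d
  x <- max(0, k - n):min(k, m)
  dens <- stats::dhyper(x, m, n, k)
  d0 <- stats::dhyper(a, m, n, k)
  ## two-sided: sum all tables no more probable than the observed one,
  ## with a small relative slack against floating-point ties
  min(1, sum(dens[dens <= d0 * (1 + 1e-7)]))
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' The p-value is the sum of hypergeometric probabilities of all tables
#' (with the observed margins) whose probability does not exceed that of
#' the observed table, with a 1e-7 relative slack for floating-point ties.
#' The table is \[a, b; c, d\] with rows = conditions and columns =
#' methylated/unmethylated read counts. All arguments are vectorized.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return numeric vector of two-sided p-values in \[0, 1\].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0) || any(!is.finite(c(a, b, c, d))))
    stop("cell counts must be non-negative finite integers", call. = FALSE)
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(a, n); b <- rep_len(b, n)
  c <- rep_len(c, n); d <- rep_len(d, n)
  vapply(seq_len(n),
         function(i) fisher_p_one(a[i], b[i], c[i], d[i]),
         numeric(1))
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment: q_(i) = min over j >= i of m * p_(j) / j,
#' clamped to 1, reported in the input order (invariant to permutation of
#' the input).
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
benjamini_hochberg <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
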