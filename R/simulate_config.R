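## Simulation configuration.

#' Zero-inflated Beta parameters for per-site methylation
#'
#' Per-site methylation in plant genomes is strongly bimodal: within a
#' compartment and context, a site is either essentially unmethylated or
#' methylated at a characteristic level. The generator therefore draws the
#' true level of each site as 0 with probability 1 - `p_meth`, and from a
#' Beta with the given mean and concentration (a = mean * conc,
#' b = (1 - mean) * conc) with probability `p_meth`. `p_meth` is thus the
#' expected fraction of methylated sites -- the quantity the
#' percentage-of-methylation summary estimates -- and the compartment mean
#' level is `p_meth * mean`.
#'
#' @param p_meth probability a site is methylated at all.
#' @param mean mean methylation level of methylated sites.
#' @param conc Beta concentration (a + b) of methylated-site levels;
#'   `Inf` gives a point mass at `mean` (degenerate Beta).
#' @return named list used in `context_levels`.
#' @export
context_level <- function(p_meth, mean = 0.85, conc = 10) {
  check_prob(p_meth, "p_meth")
  check_prob(mean, "mean")
  if (is.na(conc) || conc <= 0)
    stop("conc must be positive", call. = FALSE)
  list(p_meth = p_meth, mean = mean, conc = conc)
}

## Apple-like default: TE-hypermethylated, 5'UTR dip, CHH highest in
## promoters; genome-wide levels land near 54/38/8.5% (CG/CHG/CHH) at the
## default TE fraction.
default_context_levels <- function() {
  lv <- function(cg, chg, chh)
    list(CG = context_level(cg[1], cg[2], cg[3]),
         CHG = context_level(chg[1], chg[2], chg[3]),
         CHH = context_level(chh[1], chh[2], chh[3]))
  list(
    te         = lv(c(0.92, 0.90, 10), c(0.85, 0.80, 10), c(0.25, 0.45, 8)),
    promoter   = lv(c(0.55, 0.80, 10), c(0.40, 0.65, 10), c(0.15, 0.40, 8)),
    utr5       = lv(c(0.20, 0.70, 10), c(0.12, 0.60, 10), c(0.03, 0.35, 8)),
    cds        = lv(c(0.42, 0.75, 10), c(0.20, 0.60, 10), c(0.02, 0.35, 8)),
    intron     = lv(c(0.55, 0.80, 10), c(0.40, 0.65, 10), c(0.05, 0.35, 8)),
    utr3       = lv(c(0.32, 0.72, 10), c(0.18, 0.60, 10), c(0.04, 0.35, 8)),
    downstream = lv(c(0.48, 0.78, 10), c(0.33, 0.65, 10), c(0.07, 0.38, 8)),
    intergenic = lv(c(0.50, 0.80, 10), c(0.36, 0.65, 10), c(0.07, 0.38, 8))
  )
}

#' Simulation configuration
#'
#' Defaults mirror the study design the generator emulates: ~10x mean
#' per-cytosine coverage, bisulfite nonconversion rate 0.0012 (conversion
#' 99.88%), two biological replicates per condition, a lambda-sized
#' (48,502 bp) unmethylated spike-in chromosome, TE-rich genome with
#' apple-like context methylation, and planted DMRs of configurable
#' effect size.
#'
#' @param seed integer RNG seed; all child seeds are derived from it.
#' @param chrom_lengths integer vector of chromosome lengths (bp).
#' @param gene_count number of genes to place.
#' @param gene_structure list: `exon_count_mean`, `exon_length_mean`,
#'   `intron_length_mean`, `utr5_length`, `utr3_length`.
#' @param te_fraction fraction of the (non-spike-in) genome covered by TEs.
#' @param te_class_mix named weights over TE classes.
#' @param te_length_meanlog,te_length_sdlog log-normal TE length
#'   parameters.
#' @param context_levels per-compartment, per-context [context_level()]
#'   parameters; missing compartments fall back to `default`.
#' @param coverage_mean mean Poisson per-site read coverage.
#' @param nonconversion_rate simulated nonconversion rate r.
#' @param spike_in_length,spike_in_name unmethylated control chromosome.
#' @param n_dmrs number of DMRs planted in condition 2.
#' @param dmr_length_range planted DMR length range (bp).
#' @param dmr_effect planted absolute methylation shift (delta ML).
#' @param dmr_context context whose sites are shifted.
#' @param dmr_compartment compartment hosting planted DMRs.
#' @param dmr_direction `"both"` (alternating), `"hyper"` or `"hypo"`.
#' @param replicates_per_condition biological replicates per condition.
#' @param expression_model list: `meanlog`, `sdlog` (log-normal baseline
#'   FPKM), `nonexpressed_fraction` (FPKM < 0.1), `de_fraction`,
#'   `fold_range`, `coupling` (bias genes under planted promoter DMRs
#'   toward repression/induction), `coupling_prob`.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chrom_lengths = c(chr1 = 300000L,
                                                chr2 = 200000L),
                              gene_count = 100L,
                              gene_structure = list(),
                              te_fraction = 0.35,
                              te_class_mix = c(LTR_Gypsy = 0.45,
                                               LTR_Copia = 0.22,
                                               hAT_Tag1 = 0.08,
                                               hAT_Tip100 = 0.08,
                                               other = 0.17),
                              te_length_meanlog = 6.5,
                              te_length_sdlog = 0.6,
                              context_levels = list(),
                              coverage_mean = 10,
                              nonconversion_rate = 0.0012,
                              spike_in_length = 48502L,
                              spike_in_name = "lambda",
                              n_dmrs = 20L,
                              dmr_length_range = c(1000L, 2000L),
                              dmr_effect = 0.4,
                              dmr_context = "CG",
                              dmr_compartment = "intergenic",
                              dmr_direction = "both",
                              replicates_per_condition = 2L,
                              expression_model = list()) {
  gs_def <- list(exon_count_mean = 4, exon_length_mean = 250,
                 intron_length_mean = 150, utr5_length = 150,
                 utr3_length = 200)
  em_def <- list(meanlog = 1.0, sdlog = 1.2, nonexpressed_fraction = 0.15,
                 de_fraction = 0.10, fold_range = c(2, 6),
                 coupling = FALSE, coupling_prob = 0.6)
  cfg <- list(
    seed = as.integer(seed),
    chrom_lengths = chrom_lengths,
    gene_count = as.integer(gene_count),
    gene_structure = utils::modifyList(gs_def, gene_structure),
    te_fraction = te_fraction,
    te_class_mix = te_class_mix,
    te_length_meanlog = te_length_meanlog,
    te_length_sdlog = te_length_sdlog,
    context_levels = utils::modifyList(default_context_levels(),
                                       context_levels),
    coverage_mean = coverage_mean,
    nonconversion_rate = nonconversion_rate,
    spike_in_length = as.integer(spike_in_length),
    spike_in_name = spike_in_name,
    n_dmrs = as.integer(n_dmrs),
    dmr_length_range = as.integer(dmr_length_range),
    dmr_effect = dmr_effect,
    dmr_context = dmr_context,
    dmr_compartment = dmr_compartment,
    dmr_direction = dmr_direction,
    replicates_per_condition = as.integer(replicates_per_condition),
    expression_model = utils::modifyList(em_def, expression_model)
  )
  validate_simulation_config(cfg)
  if (is.null(names(cfg$chrom_lengths)))
    names(cfg$chrom_lengths) <- paste0("chr", seq_along(cfg$chrom_lengths))
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  check_prob(cfg$te_fraction, "te_fraction")
  check_prob(cfg$nonconversion_rate, "nonconversion_rate")
  check_prob(cfg$expression_model$nonexpressed_fraction,
             "nonexpressed_fraction")
  check_prob(cfg$expression_model$de_fraction, "de_fraction")
  if (cfg$coverage_mean <= 0)
    stop("coverage_mean must be positive", call. = FALSE)
  if (cfg$dmr_effect < 0 || cfg$dmr_effect > 1)
    stop("dmr_effect must lie in [0, 1]", call. = FALSE)
  if (!cfg$dmr_context %in% CONTEXTS)
    stop("dmr_context must be CG, CHG or CHH", call. = FALSE)
  if (!cfg$dmr_direction %in% c("both", "hyper", "hypo"))
    stop("dmr_direction must be both, hyper or hypo", call. = FALSE)
  if (any(cfg$chrom_lengths <= 0))
    stop("chromosome lengths must be positive", call. = FALSE)
  if (length(cfg$dmr_length_range) != 2L ||
      cfg$dmr_length_range[1] > cfg$dmr_length_range[2])
    stop("dmr_length_range must be c(min, max)", call. = FALSE)
  for (comp in names(cfg$context_levels))
    for (ctx in names(cfg$context_levels[[comp]])) {
      lvl <- cfg$context_levels[[comp]][[ctx]]
      if (is.na(lvl$conc) || lvl$conc <= 0)
        stop("Beta concentration must be positive (", comp, "/", ctx, ")",
             call. = FALSE)
      check_prob(lvl$p_meth, paste0("p_meth (", comp, "/", ctx, ")"))
      check_prob(lvl$mean, paste0("mean (", comp, "/", ctx, ")"))
    }
  invisible(cfg)
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("simulation_config: seed", x$seed, "|",
      length(x$chrom_lengths), "chromosome(s),",
      format(sum(x$chrom_lengths), big.mark = ","), "bp |",
      x$gene_count, "genes | TE fraction", x$te_fraction, "\n")
  cat("  coverage", x$coverage_mean, "x | r =", x$nonconversion_rate,
      "|", x$n_dmrs, x$dmr_context, "DMRs (effect",
      x$dmr_effect, ", ", x$dmr_direction, ") |",
      x$replicates_per_condition, "replicates/condition\n")
  invisible(x)
}

#' Read a simulation configuration from YAML
#'
#' Any field of [simulation_config()] may appear in the file; the rest take
#' their defaults. `context_levels` entries are given as
#' `compartment: {CG: [p_meth, mean, conc], ...}`.
#'
#' @param path YAML file.
#' @return a [simulation_config()] object.
#' @export
read_simulation_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$chrom_lengths)) y$chrom_lengths <- unlist(y$chrom_lengths)
  if (!is.null(y$context_levels)) {
    y$context_levels <- lapply(y$context_levels, function(comp)
      lapply(comp, function(v) context_level(v[[1]], v[[2]], v[[3]])))
  }
  if (!is.null(y$te_class_mix)) y$te_class_mix <- unlist(y$te_class_mix)
  if (!is.null(y$dmr_length_range))
    y$dmr_length_range <- unlist(y$dmr_length_range)
  if (!is.null(y$expression_model$fold_range))
    y$expression_model$fold_range <- unlist(y$expression_model$fold_range)
  do.call(simulation_config, y)
}
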