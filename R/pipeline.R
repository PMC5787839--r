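## End-to-end pipeline on simulated data: simulate -> methylation ->
## DMRs -> profiles -> integration, with deterministic file outputs.

write_json_det <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Run the full analysis pipeline on a simulated methylome
#'
#' Simulates a two-condition methylome from `config`, then runs every
#' analysis stage -- nonconversion estimation from the spike-in, per-site
#' methylation with correction and mC calls, 3-kb/600-bp window summaries,
#' global summaries with density tracks, 1-kb/100-bp windowed Fisher DMR
#' calling with gene/TE assignment, TE differential tests, compartment and
#' metagene/TE profiles, expression and methylation quintiles, and the
#' methylation-expression integration tables -- writing each product as a
#' plain-text file under `outdir`. Outputs are a deterministic function of
#' `config` (byte-identical across runs with the same seed).
#'
#' @param config a [simulation_config()] (or path to a YAML config).
#' @param outdir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_simulation_config(config)
  stopifnot(inherits(config, "simulation_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  emit <- function(name, writer) {
    p <- file.path(outdir, name)
    writer(p)
    paths[[name]] <<- p
  }
  main_len <- config$chrom_lengths
  spike <- config$spike_in_name

  ## -- simulate ------------------------------------------------------
  sim <- simulate_methylome(config)
  emit("genome.fa", function(p) write_fasta(sim$genome, p))
  emit("genes.gff3", function(p) write_gene_gff3(sim$genes, p))
  emit("tes.bed", function(p) write_te_bed(sim$tes, p))
  for (cond in c("control", "case")) {
    for (rr in seq_along(sim$counts[[cond]])) {
      emit(sprintf("counts_%s_rep%d.tsv", cond, rr), function(p)
        write_cytosine_report(sim$counts[[cond]][[rr]], p,
                              chrom_order = names(chrom_lengths(sim$genome))))
    }
  }
  emit("expression.tsv", function(p)
    write_expression_table(sim$expression, p))
  emit("truth_sites.tsv", function(p) {
    tr <- merge(
      sim$truth_control[, .(chrom, pos, strand, context, compartment,
                            ml_control = ml)],
      sim$truth_case[, .(chrom, pos, strand, ml_case = ml)],
      by = c("chrom", "pos", "strand"))
    data.table::fwrite(
      tr[order(factor(chrom, levels = names(chrom_lengths(sim$genome))),
               pos, strand)], p, sep = "\t")
  })
  emit("truth.json", function(p) write_json_det(list(
    r_true = config$nonconversion_rate,
    seed = config$seed,
    planted_dmrs = sim$planted,
    true_de = sim$expression[, .(gene_id, de_label)],
    site_truth_file = "truth_sites.tsv"), p))

  ## -- methylation ---------------------------------------------------
  pooled <- list(control = pool_replicates(sim$counts$control),
                 case = pool_replicates(sim$counts$case))
  nc <- estimate_nonconversion(pooled$control, spike)
  sm <- lapply(pooled, function(rep)
    compute_site_methylation(rep, r = nc$r))
  sm_called <- lapply(sm, call_methylated_sites)
  summaries <- list()
  for (cond in c("control", "case")) {
    smc <- sm_called[[cond]]
    emit(sprintf("site_methylation_%s.tsv", cond), function(p)
      data.table::fwrite(smc, p, sep = "\t"))
    w <- window_summarize(smc, main_len)
    emit(sprintf("windows_%s.tsv", cond), function(p)
      data.table::fwrite(w, p, sep = "\t"))
    gsum <- global_summary(smc[chrom != spike], main_len)
    summaries[[cond]] <- gsum
    emit(sprintf("density_%s.tsv", cond), function(p)
      write_density_track(gsum, p))
  }
  emit("summary.json", function(p) write_json_det(list(
    nonconversion_rate = nc$r,
    conversion_rate_pct = 100 * nc$conversion_rate,
    pct_methylation = lapply(summaries, function(s)
      as.list(s$pct_methylation)),
    relative_mc_proportion = lapply(summaries, function(s)
      as.list(s$relative_mc_proportion))), p))

  ## -- DMRs ----------------------------------------------------------
  dmr <- call_dmrs(sm_called$case, sm_called$control, main_len)
  emit("dmrs.bed", function(p) {
    d <- data.table::copy(dmr$dmrs)
    d[, `:=`(name = paste0(context, ":", status),
             score = round(pmin(1000, -10 * log10(pmax(q_min, 1e-100)))),
             strand = ".")]
    write_bed(d[, .(chrom, start, end, name, score, strand,
                    ml_case, ml_control)], p,
              extra_cols = c("ml_case", "ml_control"))
  })
  emit("dmr_windows.tsv", function(p)
    data.table::fwrite(dmr$windows, p, sep = "\t"))
  dmf <- assign_dmr_features(dmr$dmrs, sim$genes)
  emit("dmr_features.tsv", function(p)
    data.table::fwrite(dmf, p, sep = "\t"))
  tediff <- test_te_differential(sim$tes, sm_called$case,
                                 sm_called$control)
  emit("te_differential.tsv", function(p)
    data.table::fwrite(tediff, p, sep = "\t"))

  ## -- profiles (control condition) ----------------------------------
  smc <- sm_called$control
  emit("compartment_methylation.tsv", function(p)
    data.table::fwrite(
      compartment_methylation(smc, sim$genes, sim$tes, main_len,
                              exclude_chroms = spike), p, sep = "\t"))
  emit("metagene_profile.tsv", function(p)
    data.table::fwrite(metagene_profile(smc, sim$genes), p, sep = "\t"))
  emit("te_profile.tsv", function(p)
    data.table::fwrite(te_profile(smc, sim$tes), p, sep = "\t"))
  expr <- sim$expression
  eq <- quintile_partition(expr$fpkm_control, expr$gene_id,
                           special = expr$fpkm_control < 0.1,
                           special_label = "none")
  emit("expression_quintiles.tsv", function(p)
    data.table::fwrite(eq, p, sep = "\t"))
  eq_prof <- profile_by_group(smc, sim$genes, eq)
  emit("expression_quintile_profiles.tsv", function(p) {
    stacked <- data.table::rbindlist(eq_prof, idcol = "group")
    data.table::fwrite(stacked, p, sep = "\t")
  })
  for (reg in c("promoter", "body", "TTR")) {
    rml <- gene_region_methylation(smc, sim$genes, region = reg)
    ebm <- expression_by_methylation_group(
      expr[, .(gene_id, fpkm = fpkm_control)], rml)
    emit(sprintf("expression_by_%s_methylation.tsv", tolower(reg)),
         function(p) data.table::fwrite(ebm$summary, p, sep = "\t"))
  }
  emit("te_length_quintiles.tsv", function(p)
    data.table::fwrite(te_length_quintiles(sim$tes, smc), p, sep = "\t"))

  ## -- integration ---------------------------------------------------
  integ <- build_integration_table(dmf, expr, sim$genes)
  emit("integration.tsv", function(p)
    data.table::fwrite(integ, p, sep = "\t"))
  ov <- overlap_dmg_deg(dmf, expr)
  emit("overlap_counts.json", function(p) write_json_det(list(
    counts = as.list(ov$counts),
    enrichment_p = as.list(ov$enrichment_p),
    universe_size = ov$universe_size), p))
  gc_tab <- group_expression_comparison(
    integ$log2fc,
    integ[status_any %in% c("hyper", "both")]$log2fc,
    integ[status_any %in% c("hypo", "both")]$log2fc)
  emit("group_comparison.tsv", function(p)
    data.table::fwrite(gc_tab, p, sep = "\t"))

  invisible(unlist(paths))
}
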