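#' Run the full synthetic-study pipeline
#'
#' End-to-end flow on one simulated study: build the reference panel and
#' ground-truth compositions, simulate the multi-omic bundle and the
#' sorted-nuclei reference ChIP data, derive H3K27ac marker sites
#' (differential acetylation, peak annotation, cell-type reassignment),
#' compute all four estimators, fit the case-control differential model
#' under each configured composition adjustment, and produce concordance
#' and composition-bias reports. Every table is written as TSV (intervals
#' as BED) into `out_dir`, and a manifest lists each output with its MD5
#' checksum, the configuration hash and the seed. Identical configuration
#' and seed give bit-identical outputs.
#'
#' Stage seeds are derived from the master seed by fixed small offsets
#' (panel +0, compositions +1, study +2, sorted reference +3, shuffled
#' adjustment +4).
#'
#' @param config Configuration list, see [default_config()].
#' @param out_dir Output directory (created if needed).
#' @param seed Optional override of `config$seed`.
#' @return Invisibly, a list with the main in-memory results
#'   (`panel`, `bundle`, `truth`, `marker_sites`, `estimates`,
#'   `reference_da`, `model_da`, `bias`, `concordance`, `manifest`,
#'   `out_dir`).
#' @export
run_pipeline <- function(config = default_config(), out_dir, seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  seed <- as.integer(config$seed)
  if (is.null(seed) || is.na(seed)) cw_stop("config$seed is mandatory",
                                            class = "cellwise_config_error")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sm <- config$simulate
  ct <- cell_types()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      cw_stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
              class = "cellwise_pipeline_error")
    })
  }

  ## simulate ---------------------------------------------------------------
  panel <- stage("panel", build_reference_panel(
    n_genes = sm$n_genes, n_peaks = sm$n_peaks,
    n_meth_sites = sm$n_meth_sites,
    expr_markers_per_type = sm$expr_markers_per_type,
    peak_markers = sm$peak_markers,
    meth_markers_per_type = sm$meth_markers_per_type,
    marker_fold = sm$marker_fold, seed = seed))
  comp <- stage("compositions", draw_compositions(
    n_individuals = sm$n_individuals, alpha = sm$alpha,
    adjacency_sd = sm$adjacency_sd, neuropil_weight = sm$neuropil_weight,
    condition_shift = sm$condition_shift, seed = seed + 1L))
  sim <- stage("study", simulate_study(
    comp, panel, dispersion = sm$dispersion,
    coverage_mean = sm$coverage_mean, missing_rate = sm$missing_rate,
    da_fraction = sm$da_fraction, da_log2fc = sm$da_log2fc,
    seed = seed + 2L))
  bundle <- sim$bundle
  truth <- sim$truth
  sorted <- stage("sorted_reference",
                  simulate_sorted_chip(panel, seed = seed + 3L))

  ## markers ----------------------------------------------------------------
  mk <- config$markers
  reference_da <- stage("reference_da",
                        call_differential(sorted$counts, sorted$group))
  dars <- filter_dars(reference_da, mk$fc_fold, mk$min_mean)
  peak_gene <- annotate_peaks(panel$peaks, panel$genes, mk$upstream)
  marker_sites <- stage("marker_sites",
                        assign_marker_sites(dars, peak_gene,
                                            panel$expr_markers))

  ## estimates ---------------------------------------------------------------
  estimates <- stage("estimates", list(
    MGP = mgp(bundle$expression, panel$expr_markers),
    MSP = msp(bundle$rip_counts, marker_sites),
    WGBS_MSP = wgbs_msp(bundle$methylation_beta, panel$meth_markers,
                        bundle$methylation_coverage),
    REF = reference_proportions(bundle$expression, panel$expression)))

  ## case-control differential under the model ladder ------------------------
  meta <- bundle$sample_meta
  ts1 <- meta$sample_id[meta$tissue_sample == "TS1"]
  rip1 <- bundle$rip_counts[, ts1]
  meta1 <- meta[match(ts1, meta$sample_id), ]
  nuis <- data.frame(age_band = meta1$age_band, sex = meta1$sex)
  condition <- factor(meta1$condition, levels = c("control", "case"))
  msp_neuron <- estimates$MSP[ts1, "neuron"]
  true_nuc <- composition_matrix(truth$composition, "nuclear", ts1)

  adj_for <- function(model) {
    switch(model,
      none = adjustment_none(),
      shuffled = adjustment_shuffled(msp_neuron, seed = seed + 4L,
                                     n_levels = config$estimate$n_levels),
      ordered_factor = adjustment_ordered(msp_neuron,
                                          n_levels = config$estimate$n_levels),
      # all five log-proportions: on the log scale the simplex constraint
      # is not a collinearity, and leaving one type out leaves its marker
      # peaks unadjusted
      continuous_true = adjustment_continuous(as.data.frame(true_nuc),
                                              transform = "log"),
      cw_stop("unknown model '", model, "'", class = "cellwise_config_error"))
  }
  model_da <- stage("model_ladder", lapply(setNames(nm = config$models),
    function(mdl) fit_adjusted_da(rip1, model_spec(condition, nuis,
                                                   adj_for(mdl)))))

  ## bias assessment ----------------------------------------------------------
  region_sets <- panel_region_sets(panel)
  labels <- overlap_with_region_sets(panel$peaks, region_sets)
  bias <- stage("bias", list(
    classification = do.call(rbind, lapply(names(model_da), function(m) {
      cbind(model = m, classify_by_reference_da(model_da[[m]], reference_da))
    })),
    effect_correlation = do.call(rbind, lapply(names(model_da), function(m) {
      cbind(model = m,
            rbind(effect_size_correlation(model_da[[m]], reference_da, "all"),
                  effect_size_correlation(model_da[[m]], reference_da,
                                          "significant")))
    })),
    direction_annotation = do.call(rbind, lapply(names(model_da), function(m) {
      cbind(model = m, direction_vs_annotation(model_da[[m]], labels))
    }))))

  ## concordance ---------------------------------------------------------------
  ts2 <- meta$sample_id[meta$tissue_sample == "TS2"]
  ind <- meta1$individual_id
  neuron_cols <- cbind(
    MGP_TS1 = estimates$MGP[ts1, "neuron"],
    MGP_TS2 = estimates$MGP[ts2, "neuron"],
    REF_TS1 = estimates$REF[ts1, "neuron"],
    REF_TS2 = estimates$REF[ts2, "neuron"],
    MSP_TS1 = estimates$MSP[ts1, "neuron"],
    MSP_TS2 = estimates$MSP[ts2, "neuron"],
    WGBS_TS1 = estimates$WGBS_MSP[ts1, "neuron"],
    WGBS_TS2 = estimates$WGBS_MSP[ts2, "neuron"])
  rownames(neuron_cols) <- ind
  concordance <- stage("concordance", list(
    correlations = estimate_correlations(estimates),
    cluster = correlation_cluster(neuron_cols),
    pc_association = pc_covariate_association(
      cpm_log2(rip1),
      data.frame(condition = condition, sex = meta1$sex,
                 age = as.numeric(meta1$age_band),
                 neuron_msp = msp_neuron,
                 oligo_msp = estimates$MSP[ts1, "oligodendrocyte"]))))

  ## write outputs --------------------------------------------------------------
  outfile <- function(f) file.path(out_dir, f)
  write_matrix(bundle$expression, outfile("expression.tsv"), "gene_id")
  write_matrix(bundle$rip_counts, outfile("rip_counts.tsv"), "peak_id")
  write_methylation(bundle$methylation_beta, bundle$methylation_coverage,
                    outfile("methylation.tsv"))
  write_bed(bundle$peaks, outfile("peaks.bed"))
  write.table(meta, outfile("sample_meta.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(truth$composition, outfile("truth_composition.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$da_truth, outfile("da_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(as_panel_table(panel), outfile("panel_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(cell_type = rep(names(marker_sites),
                                         lengths(marker_sites)),
                         feature_id = unlist(marker_sites, use.names = FALSE)),
              outfile("marker_sites.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (m in names(estimates)) {
    write_matrix(unclass(estimates[[m]]),
                 outfile(paste0("estimates_", m, ".tsv")), "sample_id")
  }
  write.table(reference_da, outfile("reference_da.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (m in names(model_da)) {
    write.table(model_da[[m]], outfile(paste0("da_", m, ".tsv")), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  write.table(bias$classification, outfile("bias_classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bias$effect_correlation, outfile("bias_effect_correlation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bias$direction_annotation,
              outfile("bias_direction_annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(concordance$correlations, outfile("estimate_correlations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(position = seq_along(concordance$cluster$labels),
                         column = concordance$cluster$labels),
              outfile("cluster_order.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  pa <- concordance$pc_association
  write.table(data.frame(variable = rownames(pa$p_values), pa$p_values,
                         check.names = FALSE),
              outfile("pc_association.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write_config(config, outfile("config.yaml"))

  files <- sort(setdiff(list.files(out_dir), "manifest.tsv"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- data.frame(
    file = files, md5 = unname(sums),
    config_hash = unname(tools::md5sum(outfile("config.yaml"))),
    seed = seed, stringsAsFactors = FALSE)
  write.table(manifest, outfile("manifest.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  invisible(list(panel = panel, bundle = bundle, truth = truth,
                 marker_sites = marker_sites, estimates = estimates,
                 reference_da = reference_da, model_da = model_da,
                 bias = bias, concordance = concordance,
                 manifest = manifest, out_dir = out_dir))
}
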