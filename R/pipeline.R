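# End-to-end orchestration of the synthetic analysis: simulate, call,
# cluster, enrich, regionalize, bootstrap. The numbered scripts under
# analysis/ are thin drivers over this function and the stage functions.

#' Run the full synthetic analysis end to end
#'
#' Simulates a dataset, calls target-lineage mutations by outgroup-confirmed
#' parsimony (masking the simulated repeat track when present), chains and
#' classifies clusters, filters them at the cluster P-value threshold,
#' computes the motif-panel enrichment and the 48-trinucleotide scan, defines
#' the A3G-induced mutation set, and runs the functional-region fold-change
#' analyses with block-bootstrap standard errors.
#'
#' @param config a [simulation_config()].
#' @param outdir optional directory; when given, stage outputs (TSV) and a
#'   run manifest (YAML) are written there.
#' @param max_spacing cluster chaining distance (bp).
#' @param min_spacing_complex complex-mutation exclusion distance (bp).
#' @param p_threshold cluster P-value threshold defining the A3G set.
#' @param n_boot bootstrap replicates for standard errors.
#' @param block_size block size for the bootstrap scheme.
#' @return list with the stage objects: `sim`, `ms` (mutation_set), `cs`
#'   (classified cluster_set), `cs_sig` (P-value-filtered), `panel`
#'   (motif-panel enrichment), `scan` (48-trinucleotide scan), `a3g`
#'   (A3G clusters and mutation set), `regions` (fold-change table),
#'   `expression` (decile correlation), `confidence` (enrichment vs
#'   confidence), `boot` (bootstrap SE of E(CCC)).
#' @export
run_synthetic_analysis <- function(config, outdir = NULL, max_spacing = 50,
                                   min_spacing_complex = 10,
                                   p_threshold = 0.01, n_boot = 200,
                                   block_size = 90000) {
  sim <- simulate_dataset(config)
  masks <- sim$annotations["repeat_mask"]
  masks <- masks[!vapply(masks, is.null, logical(1))]
  ms <- call_mutations(sim$alignment, masks = if (length(masks)) masks else NULL)

  cs <- detect_clusters(ms, max_spacing = max_spacing)
  cs <- exclude_complex(cs, min_spacing = min_spacing_complex)
  cs <- classify_clusters(cs)
  cs_sig <- filter_by_pvalue(cs, p_threshold)

  panel <- motif_enrichment(cs_sig, a3g_motif_panel(), background = "genomic")
  scan <- trinucleotide_scan(cs_sig)
  a3g <- define_a3g_clusters(cs_sig)
  control <- ms$mutations[!(ms$mutations$pos0 %in% a3g$mutations$pos0), , drop = FALSE]

  # keep at least ~20 blocks so resampling is informative on small genomes
  block_size <- min(block_size, floor(sum(ms$genome_length) / 20))
  scheme <- make_blocks(ms$genome_length, block_size = block_size)
  boot <- bootstrap_enrichment(cs_sig, motif_ccc(), scheme = scheme,
                               n_boot = n_boot, seed = config$seed)

  region_panel <- sim$annotations[setdiff(names(sim$annotations),
                                          c("repeat_mask", "expression"))]
  regions <- if (length(region_panel) && nrow(a3g$mutations) && nrow(control)) {
    region_panel_fold_change(a3g$mutations, control, region_panel)
  } else NULL

  expression <- NULL
  if (!is.null(sim$annotations$expression) && nrow(a3g$mutations) &&
      nrow(control)) {
    expression <- tryCatch(
      expression_decile_correlation(a3g$mutations, control,
                                    sim$annotations$expression),
      error = function(e) NULL)
  }

  confidence <- enrichment_vs_confidence(
    cs, thresholds = c(0.05, 0.01, 0.001, 1e-4), motif = motif_ccc())

  out <- list(sim = sim, ms = ms, cs = cs, cs_sig = cs_sig, panel = panel,
              scan = scan, a3g = a3g, control = control, regions = regions,
              expression = expression, confidence = confidence, boot = boot,
              params = list(max_spacing = max_spacing,
                            min_spacing_complex = min_spacing_complex,
                            p_threshold = p_threshold, n_boot = n_boot,
                            block_size = block_size))
  if (!is.null(outdir)) write_analysis_outputs(out, outdir)
  out
}

write_analysis_outputs <- function(res, outdir) {
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  write_mutations_tsv(res$ms$mutations, file.path(outdir, "mutations.tsv"))
  utils::write.table(res$cs$clusters, file.path(outdir, "clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$panel, file.path(outdir, "motif_panel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$scan, file.path(outdir, "trinucleotide_scan.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(res$regions)) {
    utils::write.table(res$regions, file.path(outdir, "region_fold_change.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("a3gclust")),
    seed = res$sim$config$seed,
    genome_length = res$sim$config$genome_length,
    params = res$params,
    n_mutations = nrow(res$ms$mutations),
    n_clusters = nrow(res$cs$clusters),
    n_a3g_clusters = nrow(res$a3g$clusters))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  invisible(outdir)
}
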