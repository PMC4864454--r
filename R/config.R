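#' Simulation configuration for the synthetic four-taxon dataset
#'
#' Builds and validates the configuration object consumed by
#' [simulate_dataset()] and the individual generator stages. The defaults
#' describe a compact but realistic study condition: a human-like base
#' composition (41% GC, CpG-depleted to 0.25 of the random expectation),
#' per-branch substitution rates on the scale of great-ape divergences,
#' CpG hypermutation at ten times the base rate, and A3G cluster events of
#' two to five same-strand cytosine deaminations planted at CC/CCC motifs
#' within a 50-bp chaining span.
#'
#' @param genome_length ancestral genome length in bp (single chromosome).
#' @param gc_fraction target G+C proportion of the ancestral sequence.
#' @param cpg_enrichment multiplier on the CG dinucleotide frequency relative
#'   to the independent-base expectation; values below 1 model the CpG
#'   depletion of vertebrate genomes.
#' @param branch_rates named per-bp substitution probabilities for the
#'   branches `target`, `sister`, `internal`, `outgroup1`, `outgroup2` of the
#'   ((target,sister),outgroup1,outgroup2) tree. Each must lie in [0, 0.1]:
#'   the parsimony caller assumes low homoplasy.
#' @param a3g_event_rate planted deaminase events per bp on the target branch.
#' @param a3g_event_size named probability vector over event sizes (numbers of
#'   mutations per event); names are the sizes, support must lie in 2..10.
#' @param a3g_span maximum spacing in bp between consecutive mutations of one
#'   event (the cluster-chaining window).
#' @param min_event_spacing minimum spacing between consecutive event
#'   mutations; the default 11 (spacing drawn in (10, a3g_span]) keeps planted
#'   events clear of the pipeline's complex-mutation exclusion at 10 bp.
#' @param a3g_c_to_t_fraction proportion of event mutations that are C>T
#'   (the remainder split evenly between C>G and C>A).
#' @param motif_fidelity per-mutation probability of placement at the mutated
#'   (3') position of a CCC context; the remainder go to CC-but-not-CCC
#'   contexts.
#' @param cpg_hypermutation_multiplier rate multiplier at CpG cytosines (and
#'   guanines) on every branch, biased towards C>T (G>A) transitions.
#' @param reverse_strand_prob probability that an event is planted on the
#'   reverse strand (G positions in GG/GGG contexts); 0.5 models a
#'   strand-symmetric free enzyme.
#' @param lineage_labels labels of the three descendant lineages used for the
#'   allele-track partition of target-branch mutations.
#' @param lineage_proportions named probabilities over `common` plus each
#'   lineage label; must sum to 1.
#' @param annotation_spec list of annotation track descriptions, each a list
#'   with `label`, `n` (interval count), `length` (interval length in bp) and
#'   optional `scored = TRUE` for expression-style tracks carrying lognormal
#'   levels.
#' @param a3g_weight_by optional label of a scored annotation track; when set,
#'   event anchors are sampled inside that track's intervals with probability
#'   proportional to interval level (times length), emulating
#'   transcription-coupled deaminase exposure.
#' @param chrom chromosome name used in all outputs.
#' @param seed integer RNG seed; identical configs give byte-identical output.
#' @return a validated object of class `simulation_config`.
#' @export
simulation_config <- function(genome_length = 2e6,
                              gc_fraction = 0.41,
                              cpg_enrichment = 0.25,
                              branch_rates = c(target = 0.005, sister = 0.005,
                                               internal = 0.002,
                                               outgroup1 = 0.02, outgroup2 = 0.06),
                              a3g_event_rate = 1e-4,
                              a3g_event_size = c("2" = 8, "3" = 4, "4" = 2, "5" = 1) / 15,
                              a3g_span = 50,
                              min_event_spacing = 11,
                              a3g_c_to_t_fraction = 0.7,
                              motif_fidelity = 0.8,
                              cpg_hypermutation_multiplier = 10,
                              reverse_strand_prob = 0.5,
                              lineage_labels = c("modern", "neandertal", "denisovan"),
                              lineage_proportions = c(common = 0.7, modern = 0.1,
                                                      neandertal = 0.1, denisovan = 0.1),
                              annotation_spec = NULL,
                              a3g_weight_by = NULL,
                              chrom = "chr1",
                              seed = 1L) {
  cfg <- list(
    genome_length = as.integer(genome_length),
    gc_fraction = gc_fraction,
    cpg_enrichment = cpg_enrichment,
    branch_rates = branch_rates,
    a3g_event_rate = a3g_event_rate,
    a3g_event_size = a3g_event_size,
    a3g_span = as.integer(a3g_span),
    min_event_spacing = as.integer(min_event_spacing),
    a3g_c_to_t_fraction = a3g_c_to_t_fraction,
    motif_fidelity = motif_fidelity,
    cpg_hypermutation_multiplier = cpg_hypermutation_multiplier,
    reverse_strand_prob = reverse_strand_prob,
    lineage_labels = lineage_labels,
    lineage_proportions = lineage_proportions,
    annotation_spec = annotation_spec %||% default_annotation_spec(genome_length),
    a3g_weight_by = a3g_weight_by,
    chrom = chrom,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
}

#' Default annotation tracks for the synthetic genome
#'
#' Tracks scale with genome length: broad transcribed intervals, short exons,
#' kb-scale regulatory intervals, a repeat mask, and a scored expression track
#' whose interval levels are drawn lognormally.
#'
#' @param genome_length genome length in bp.
#' @return list of annotation descriptions for [simulation_config()].
#' @export
default_annotation_spec <- function(genome_length) {
  L <- genome_length
  n_tx <- max(4L, round(L / 1e5))
  n_ex <- max(10L, round(L / 1e4))
  list(
    list(label = "transcribed", n = n_tx,
         length = min(20000L, as.integer(L / n_tx / 2))),
    list(label = "exons", n = n_ex, length = min(300L, as.integer(L / n_ex / 2))),
    list(label = "regulatory", n = max(5L, round(L / 4e4)), length = 1000L),
    list(label = "repeat_mask", n = max(2L, round(L / 8e4)), length = 2000L),
    list(label = "expression", n = max(12L, round(L / 1e5)),
         length = min(20000L, as.integer(L / max(12L, round(L / 1e5)) / 2)),
         scored = TRUE)
  )
}

validate_simulation_config <- function(cfg) {
  if (!inherits(cfg, "simulation_config")) stop("not a simulation_config")
  if (is.na(cfg$genome_length) || cfg$genome_length < 1000) {
    stop("configuration error: 'genome_length' must be at least 1000 bp")
  }
  assert_probability(cfg$gc_fraction, "gc_fraction")
  if (!is.numeric(cfg$cpg_enrichment) || cfg$cpg_enrichment < 0) {
    stop("configuration error: 'cpg_enrichment' must be a non-negative multiplier")
  }
  need <- c("target", "sister", "internal", "outgroup1", "outgroup2")
  if (!all(need %in% names(cfg$branch_rates))) {
    stop("configuration error: 'branch_rates' must name branches ",
         paste(need, collapse = ", "))
  }
  if (any(cfg$branch_rates < 0) || any(cfg$branch_rates > 0.1)) {
    stop("configuration error: 'branch_rates' must lie in [0, 0.1] ",
         "(higher rates violate the low-homoplasy assumption of the parsimony caller)")
  }
  if (cfg$a3g_event_rate < 0) {
    stop("configuration error: 'a3g_event_rate' must be non-negative")
  }
  sizes <- as.integer(names(cfg$a3g_event_size))
  if (anyNA(sizes) || any(sizes < 2) || any(sizes > 10)) {
    stop("configuration error: 'a3g_event_size' support must lie in 2..10")
  }
  if (any(cfg$a3g_event_size < 0) || abs(sum(cfg$a3g_event_size) - 1) > 1e-8) {
    stop("configuration error: 'a3g_event_size' must be a probability vector")
  }
  if (cfg$a3g_span <= cfg$min_event_spacing) {
    stop("configuration error: 'a3g_span' must exceed 'min_event_spacing'")
  }
  assert_probability(cfg$a3g_c_to_t_fraction, "a3g_c_to_t_fraction")
  assert_probability(cfg$motif_fidelity, "motif_fidelity")
  assert_probability(cfg$reverse_strand_prob, "reverse_strand_prob")
  if (cfg$cpg_hypermutation_multiplier < 0) {
    stop("configuration error: 'cpg_hypermutation_multiplier' must be non-negative")
  }
  lp <- cfg$lineage_proportions
  if (!setequal(names(lp), c("common", cfg$lineage_labels)) ||
      abs(sum(lp) - 1) > 1e-8 || any(lp < 0)) {
    stop("configuration error: 'lineage_proportions' must be probabilities over ",
         "'common' and each lineage label, summing to 1")
  }
  for (a in cfg$annotation_spec) {
    if (!all(c("label", "n", "length") %in% names(a))) {
      stop("configuration error: 'annotation_spec' entries need label, n, length")
    }
    if (a$length >= cfg$genome_length) {
      stop("configuration error: 'annotation_spec' interval length exceeds genome")
    }
  }
  if (!is.null(cfg$a3g_weight_by)) {
    labs <- vapply(cfg$annotation_spec, `[[`, character(1), "label")
    if (!cfg$a3g_weight_by %in% labs) {
      stop("configuration error: 'a3g_weight_by' names an unknown annotation track")
    }
  }
  cfg
}
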