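# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A small planted dataset exercising the full pipeline.
planted_fixture <- function() {
  cached("planted", {
    cfg <- simulation_config(
      genome_length = 3e5, seed = 101,
      branch_rates = c(target = 1e-3, sister = 1e-3, internal = 2e-3,
                       outgroup1 = 0.02, outgroup2 = 0.06),
      a3g_event_rate = 60 / 3e5)
    sim <- simulate_dataset(cfg)
    ms <- call_mutations(sim$alignment, masks = sim$annotations["repeat_mask"])
    cs <- classify_clusters(exclude_complex(detect_clusters(ms)))
    list(cfg = cfg, sim = sim, ms = ms, cs = cs)
  })
}

# A null dataset (no planted events, homogeneous rates).
null_fixture <- function() {
  cached("null", {
    cfg <- simulation_config(
      genome_length = 4e5, seed = 202,
      branch_rates = c(target = 3e-3, sister = 3e-3, internal = 2e-3,
                       outgroup1 = 0.02, outgroup2 = 0.06),
      a3g_event_rate = 0, cpg_hypermutation_multiplier = 1)
    sim <- simulate_dataset(cfg)
    ms <- call_mutations(sim$alignment)
    cs <- classify_clusters(exclude_complex(detect_clusters(ms)))
    list(cfg = cfg, sim = sim, ms = ms, cs = cs)
  })
}

# Minimal hand-built mutation_set: a genome string plus mutated positions.
toy_mutation_set <- function(seq, pos0, anc = NULL, der = NULL,
                             chrom = "chr1") {
  ch <- strsplit(seq, "")[[1]]
  if (is.null(anc)) anc <- ch[pos0 + 1L]
  if (is.null(der)) {
    der <- vapply(anc, function(a) setdiff(c("A", "C", "G", "T"), a)[1],
                  character(1))
  }
  mutation_set(
    data.frame(chrom = chrom, pos0 = pos0, anc = anc, der = der),
    stats::setNames(list(seq), chrom))
}
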