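# Synthetic data generator: composition, determinism, branch mutations,
# planted events, truth-table conservation.

test_that("identical config and seed reproduce the genome and annotations", {
  cfg <- simulation_config(genome_length = 50000, seed = 11)
  g1 <- generate_ancestral_genome(cfg)
  g2 <- generate_ancestral_genome(cfg)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$annotations, g2$annotations)
  g3 <- generate_ancestral_genome(simulation_config(genome_length = 50000, seed = 12))
  expect_false(identical(g1$sequence, g3$sequence))
})

test_that("base composition tracks gc_fraction and cpg_enrichment", {
  cfg0 <- simulation_config(genome_length = 5000, gc_fraction = 0, seed = 1)
  s0 <- generate_ancestral_genome(cfg0)$sequence
  expect_true(all(strsplit(s0, "")[[1]] %in% c("A", "T")))

  L <- 2e5
  gc_of <- function(s) {
    ch <- strsplit(s, "")[[1]]
    mean(ch %in% c("C", "G"))
  }
  cg_freq <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(ch[-length(ch)] == "C" & ch[-1] == "G") / (length(ch) - 1)
  }
  seqs <- lapply(c(0.25, 1, 2), function(m) {
    generate_ancestral_genome(simulation_config(
      genome_length = L, gc_fraction = 0.41, cpg_enrichment = m, seed = 5))$sequence
  })
  for (s in seqs) expect_lt(abs(gc_of(s) - 0.41), 0.02)
  cg <- vapply(seqs, cg_freq, numeric(1))
  expect_true(cg[1] < cg[2] && cg[2] < cg[3])
  base <- (0.41 / 2)^2
  expect_lt(abs(cg[1] / base - 0.25), 0.1)
  expect_lt(abs(cg[3] / base - 2), 0.4)
})

test_that("branch mutation counts follow the binomial expectation", {
  cfg <- simulation_config(genome_length = 2e5, seed = 3)
  s <- generate_ancestral_genome(cfg)$sequence
  rates <- c(target = 1e-3, sister = 0, internal = 0,
             outgroup1 = 0, outgroup2 = 0)
  muts <- simulate_branch_mutations(s, rates, cpg_hypermutation_multiplier = 1,
                                    seed = 4)
  expect_identical(nrow(muts$sister), 0L)
  n <- nrow(muts$target)
  expected <- 2e5 * 1e-3
  sigma <- sqrt(2e5 * 1e-3 * (1 - 1e-3))
  expect_lt(abs(n - expected), 4 * sigma)
  # no site mutated twice, derived always differs from ancestral
  expect_false(any(duplicated(muts$target$pos0)))
  expect_true(all(muts$target$anc != muts$target$der))
})

test_that("CpG hypermutation raises the C>T rate at CpG sites", {
  cfg <- simulation_config(genome_length = 2e5, cpg_enrichment = 1, seed = 6)
  s <- generate_ancestral_genome(cfg)$sequence
  ch <- strsplit(s, "")[[1]]
  cpg_c <- c(ch[-length(ch)] == "C" & ch[-1] == "G", FALSE)
  n_cpg_c <- sum(cpg_c & ch == "C")
  n_other_c <- sum(!cpg_c & ch == "C")
  muts <- simulate_branch_mutations(
    s, c(target = 1e-3, sister = 0, internal = 0, outgroup1 = 0, outgroup2 = 0),
    cpg_hypermutation_multiplier = 10, seed = 7)$target
  ct <- muts[muts$anc == "C" & muts$der == "T", ]
  rate_cpg <- sum(cpg_c[ct$pos0 + 1]) / n_cpg_c
  rate_other <- sum(!cpg_c[ct$pos0 + 1]) / n_other_c
  expect_gt(rate_cpg, rate_other)
})

test_that("invalid configurations fail fast, naming the offending field", {
  expect_error(simulation_config(genome_length = 100), "genome_length")
  expect_error(simulation_config(gc_fraction = 1.2), "gc_fraction")
  expect_error(simulation_config(branch_rates = c(
    target = 0.2, sister = 0, internal = 0, outgroup1 = 0, outgroup2 = 0)),
    "branch_rates")
  expect_error(simulation_config(a3g_event_size = c("1" = 0.5, "2" = 0.5)),
               "a3g_event_size")
  expect_error(simulate_branch_mutations("ACGT", c(x = 0.5)), "0.1")
})

test_that("planted events sit at the configured motifs with legal spacing", {
  cfg <- simulation_config(genome_length = 2e5, seed = 9, motif_fidelity = 1,
                           a3g_event_rate = 30 / 2e5)
  set.seed(9)
  s <- a3gclust:::gen_genome_sequence(cfg)
  ev <- plant_a3g_events(s, cfg, seed = 10)
  expect_gt(nrow(ev), 0)
  ch <- strsplit(s, "")[[1]]
  for (i in seq_len(nrow(ev))) {
    p <- ev$pos0[i] + 1
    if (ev$strand[i] == "+") {
      expect_identical(paste(ch[(p - 2):p], collapse = ""), "CCC")
      expect_identical(ev$anc[i], "C")
    } else {
      expect_identical(paste(ch[p:(p + 2)], collapse = ""), "GGG")
      expect_identical(ev$anc[i], "G")
    }
  }
  spacings <- unlist(lapply(split(ev$pos0, ev$event_id), function(p) diff(sort(p))))
  expect_true(all(spacings > 10 & spacings <= cfg$a3g_span))
  sizes <- table(ev$event_id)
  expect_true(all(sizes >= 2 & sizes <= 5))
  # zero rate plants nothing
  cfg0 <- simulation_config(genome_length = 2e5, seed = 9, a3g_event_rate = 0)
  expect_identical(nrow(plant_a3g_events(s, cfg0, seed = 10)), 0L)
})

test_that("planting fails informatively when motifs are too sparse", {
  cfg <- simulation_config(genome_length = 5000, gc_fraction = 0.02,
                           a3g_event_rate = 0.1, seed = 2)
  set.seed(2)
  s <- a3gclust:::gen_genome_sequence(cfg)
  expect_error(plant_a3g_events(s, cfg, seed = 3), "insufficient motif density")
})

test_that("the truth table records every target-branch difference exactly once", {
  fx <- planted_fixture()
  tgt <- strsplit(fx$sim$alignment$seqs[["target"]], "")[[1]]
  anc <- strsplit(fx$sim$target_ancestor, "")[[1]]
  diffs <- which(tgt != anc) - 1L
  expect_setequal(diffs, fx$sim$truth$pos0)
  expect_false(any(duplicated(fx$sim$truth$pos0)))
  expect_identical(anc[fx$sim$truth$pos0 + 1], fx$sim$truth$anc)
  expect_identical(tgt[fx$sim$truth$pos0 + 1], fx$sim$truth$der)
  # planted mutations only on ancestral C (plus) / G (minus)
  a3g <- fx$sim$truth[fx$sim$truth$event_class == "a3g", ]
  expect_true(all(a3g$anc[a3g$strand == "+"] == "C"))
  expect_true(all(a3g$anc[a3g$strand == "-"] == "G"))
})

test_that("identical configs give byte-identical datasets", {
  cfg <- simulation_config(genome_length = 50000, seed = 33)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  expect_identical(s1$alignment$seqs, s2$alignment$seqs)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$annotations, s2$annotations)
})
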