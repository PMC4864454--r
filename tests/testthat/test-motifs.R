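# Motif matching, signals, the four backgrounds, exact tests, the
# 48-trinucleotide scan and the CpG controls.

test_that("motif construction validates pattern and mutated position", {
  expect_error(motif("CCCCC", 2), "length")
  expect_error(motif("CX", 1), "A, C, G, T")
  expect_error(motif("CC", 5), "outside")
  expect_error(motif("TCW", 2), "must be C")  # W is not exactly C
  m <- motif("WRC", 2, "AID")
  expect_identical(m$pattern, "WRC")
})

test_that("window matching honors strand and IUPAC semantics", {
  ccc <- motif_ccc()
  # plus strand: ...ACCCG..., mutated base = 3'-most C (window center)
  expect_true(match_motif("ACCCGAA", ccc, "+"))
  # minus strand: ...CGGGT..., mutated base = 5'-most G (window center)
  expect_true(match_motif("TACGGGT", ccc, "-"))
  expect_false(match_motif("TACGGGT", ccc, "+"))
  # W excludes C: TCW must not match a TCC window
  tcw <- motif("TCW", 1)
  expect_false(match_motif("ATCCA", tcw, "+"))
  expect_true(match_motif("ATCAA", tcw, "+"))
  expect_true(match_motif("ATCTA", tcw, "+"))
  expect_error(match_motif("CC", ccc, "+"), "odd-length")
  expect_error(match_motif("C", ccc, "+"), "shorter")
})

test_that("the clustered-mutation signal counts motif matches exactly", {
  # constructed fixture: 100 clustered C mutations, 30 in CCC context
  blocks <- character(50)
  for (i in 1:50) {
    # two mutations per cluster, 20 bp apart, cluster blocks 200 bp apart
    left <- if (i <= 15) "CC" else "AA"   # first mutation CCC for i<=15
    right <- if (i <= 15) "CC" else "AA"  # second mutation CCC for i<=15
    blocks[i] <- paste0(strrep("T", 78), left, "C", strrep("T", 19), right,
                        "C", strrep("T", 97))
  }
  seq <- paste(blocks, collapse = "")
  stopifnot(nchar(seq) == 10000)
  base <- (seq_len(50) - 1) * 200
  pos <- sort(c(base + 80, base + 102))
  ms <- toy_mutation_set(seq, pos0 = as.integer(pos))
  expect_true(all(strsplit(seq, "")[[1]][pos + 1] == "C"))
  cs <- classify_clusters(detect_clusters(ms), callable_length = nchar(seq))
  expect_identical(nrow(cs$clusters), 50L)
  sig <- motif_signal(cs, motif_ccc())
  expect_identical(sig$n_total, 100L)
  expect_identical(sig$n_match, 30L)
  expect_equal(sig$ratio, 0.30)
})

test_that("genomic background equals the naive position scan", {
  set.seed(13)
  seq <- random_dna(20000)
  for (mf in list(motif_ccc(), motif("TCW", 1), motif("WRC", 2), motif_cc())) {
    bg <- genomic_background(seq, mf)
    ch <- strsplit(seq, "")[[1]]
    expect_equal(bg$n_motif, naive_motif_count(seq, mf$pattern, mf$mutated_index))
    expect_equal(bg$n_base, sum(ch %in% c("C", "G")))
  }
  # saturation: a CCC-repeat genome backgrounds to ~1 (edge effects only)
  sat <- genomic_background(strrep("C", 1000), motif_ccc())
  expect_gt(sat$ratio, 0.99)
  expect_error(genomic_background(strrep("AT", 500), motif_ccc()), "no C or G")
})

test_that("enrichment combines signal and background with an exact test", {
  e <- enrichment(list(ratio = 0.30, n_match = 30, n_total = 100),
                  list(ratio = 0.15, n_motif = 1500, n_base = 10000))
  expect_equal(e$E, 2.0)
  # Fisher one-tailed p equals the hypergeometric tail enumeration
  p_oracle <- fisher_greater_oracle(30, 70, 1500, 8500)
  e2 <- enrichment(list(ratio = 0.3, n_match = 30, n_total = 100),
                   list(ratio = 0.15, n_motif = 1500, n_base = 10000))
  expect_equal(e2$fisher_p, p_oracle, tolerance = 1e-10)
  # null: signal == background gives E = 1 and p >= 0.5
  e3 <- enrichment(list(ratio = 0.2, n_match = 200, n_total = 1000),
                   list(ratio = 0.2, n_motif = 2000, n_base = 10000))
  expect_equal(e3$E, 1)
  expect_gte(e3$fisher_p, 0.5)
  # zero background flags infinite E instead of erroring
  e4 <- enrichment(list(ratio = 0.1, n_match = 1, n_total = 10),
                   list(ratio = 0, n_motif = 0, n_base = 100))
  expect_identical(e4$E, Inf)
})

test_that("the trinucleotide scan emits 48 tests and matches the dedicated run", {
  fx <- planted_fixture()
  cs <- filter_by_pvalue(fx$cs, 0.01)
  scan <- trinucleotide_scan(cs)
  expect_identical(nrow(scan), 48L)
  expect_identical(sum(scan$pattern == "CCC"), 3L)  # one per register
  # CCC at the 3' register equals the dedicated A3G-CCC motif run
  ded <- motif_enrichment(cs, list(motif_ccc()), background = "genomic")
  row <- scan[scan$pattern == "CCC" & scan$mutated_index == 2, ]
  expect_equal(row$signal, ded$signal)
  expect_equal(row$E, ded$E)
  expect_equal(row$fisher_p, ded$fisher_p)
  # CpG flags cover exactly the CG-containing patterns
  expect_identical(scan$cpg, grepl("CG", scan$pattern))
  # under planted A3G signal, CCC@2 tops the CpG-free ranking
  free <- scan[!scan$cpg, ]
  expect_identical(free$label[which.max(free$E)], "CCC:2")
  expect_lt(free$q[free$label == "CCC:2"], 0.05)
})

test_that("every E is strand-symmetric under reverse complement", {
  fx <- planted_fixture()
  ms <- call_mutations(fx$sim$alignment)
  cs <- classify_clusters(exclude_complex(detect_clusters(ms)))
  ms_rc <- call_mutations(revcomp_alignment(fx$sim$alignment))
  cs_rc <- classify_clusters(exclude_complex(detect_clusters(ms_rc)))
  pan <- motif_enrichment(cs, a3g_motif_panel(), background = "genomic")
  pan_rc <- motif_enrichment(cs_rc, a3g_motif_panel(), background = "genomic")
  expect_equal(pan$signal, pan_rc$signal, tolerance = 1e-12)
  expect_equal(pan$background, pan_rc$background, tolerance = 1e-12)
  expect_equal(pan$E, pan_rc$E, tolerance = 1e-12)
})

test_that("randomized backgrounds are reproducible and centered on the genome", {
  fx <- planted_fixture()
  cs <- fx$cs
  b1 <- random_mutation_background(cs, motif_ccc(), n_sets = 20, seed = 5)
  b2 <- random_mutation_background(cs, motif_ccc(), n_sets = 20, seed = 5)
  expect_identical(b1$per_set, b2$per_set)
  gb <- genomic_background(fx$ms, motif_ccc())
  # randomized mutations form chance clusters whose motif fraction estimates
  # the genomic C/G-conditional rate
  se <- stats::sd(b1$per_set, na.rm = TRUE) / sqrt(sum(!is.na(b1$per_set)))
  expect_lt(abs(b1$ratio - gb$ratio), 4 * max(se, 0.01))

  rc1 <- random_cluster_background(cs, motif_ccc(), n_sets = 20, seed = 6)
  rc2 <- random_cluster_background(cs, motif_ccc(), n_sets = 20, seed = 6)
  expect_identical(rc1$per_set, rc2$per_set)
  se_rc <- stats::sd(rc1$per_set, na.rm = TRUE) / sqrt(sum(!is.na(rc1$per_set)))
  expect_lt(abs(rc1$ratio - gb$ratio), 4 * max(se_rc, 0.01))
})

test_that("relocated clusters on a uniform-C genome saturate the CC background", {
  seq <- strrep("C", 2000)
  ms <- toy_mutation_set(seq, pos0 = c(100L, 130L, 500L, 540L))
  cs <- classify_clusters(detect_clusters(ms), callable_length = 2000)
  bg <- random_cluster_background(cs, motif_cc(), n_sets = 5, seed = 1)
  expect_equal(bg$ratio, 1)
})

test_that("local-context background tracks composition gradients", {
  fx <- planted_fixture()
  lc <- local_context_background(fx$cs, motif_ccc(), window = 10000)
  gb <- genomic_background(fx$ms, motif_ccc())
  # homogeneous genome: local equals genomic within sampling noise
  expect_lt(abs(lc$ratio - gb$ratio) / gb$ratio, 0.25)
  # constructed gradient: clusters in the GC-rich half see a higher local
  # CCC background than the genome-wide value
  set.seed(31)
  at_half <- random_dna(50000, gc = 0.20)
  gc_half <- random_dna(50000, gc = 0.70)
  seq <- paste0(at_half, gc_half)
  ch <- strsplit(seq, "")[[1]]
  cpos <- which(ch == "C") - 1L
  # two C-cluster pairs planted in the GC-rich half
  pick <- sort(c(cpos[cpos >= 60000 & cpos <= 60040][1:2],
                 cpos[cpos >= 80000 & cpos <= 80040][1:2]))
  ms <- toy_mutation_set(seq, pos0 = pick)
  cs <- classify_clusters(detect_clusters(ms), callable_length = 100000)
  lc2 <- local_context_background(cs, motif_ccc(), window = 10000)
  gb2 <- genomic_background(seq, motif_ccc())
  expect_gt(lc2$ratio, gb2$ratio)
})

test_that("CpG controls separate deaminase signal from CpG deamination", {
  fx <- planted_fixture()
  cs <- filter_by_pvalue(fx$cs, 0.01)
  ctl <- cpg_controls(cs)
  # planted A3G signal survives both controls
  expect_gt(ctl$cpg_masked$E, 1)
  expect_gt(ctl$cccg_excluded$E, 1)
  add <- ctl$additivity
  expect_setequal(add$stratum, c("motif", "cpg", "motif_and_cpg", "neither"))
  # a CCCG-context mutation counts in the motif, cpg and intersection strata
  seqc <- paste0(strrep("A", 50), "CCCG", strrep("A", 50))
  msc <- toy_mutation_set(seqc, pos0 = 52L)  # the 3' C of CCC, followed by G
  addc <- a3gclust:::cpg_additivity(msc, motif_ccc())
  expect_identical(addc$mutations[addc$stratum == "motif"], 1)
  expect_identical(addc$mutations[addc$stratum == "cpg"], 1)
  expect_identical(addc$mutations[addc$stratum == "motif_and_cpg"], 1)
  expect_identical(addc$mutations[addc$stratum == "neither"], 0)
})

test_that("enrichment rises with cluster confidence on planted data", {
  fx <- planted_fixture()
  res <- enrichment_vs_confidence(fx$cs, thresholds = c(0.05, 0.01, 0.001),
                                  motif = motif_ccc())
  expect_identical(nrow(res$table), 3L)
  expect_true(is.finite(res$r))
  expect_error(enrichment_vs_confidence(fx$cs, thresholds = c(0.05, 0.01)),
               "at least 3")
})

test_that("subset enrichment restricts the signal to regions", {
  fx <- planted_fixture()
  cs <- fx$cs
  whole <- data.frame(chrom = "chr1", start0 = 0,
                      end0 = fx$cfg$genome_length)
  full <- subset_enrichment(cs, motif_ccc(), regions = whole)
  unrestricted <- subset_enrichment(cs, motif_ccc())
  expect_equal(full$E, unrestricted$E)
  empty <- data.frame(chrom = "chr1", start0 = 0, end0 = 1)
  expect_error(subset_enrichment(cs, motif_ccc(), regions = empty),
               "undefined signal")
  # clustered mutations carry more planted signal than nonclustered ones
  nc <- subset_enrichment(cs, motif_ccc(), set = "nonclustered")
  expect_gt(unrestricted$E, nc$E)
})
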