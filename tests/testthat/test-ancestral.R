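# Parsimony ancestral inference, masking, mutation calling and the lineage
# partition.

make_columns <- function(target, sister, out1, out2, chrom = "chr1") {
  data.frame(chrom = chrom, pos0 = seq_along(target) - 1L,
             target = target, sister = sister, out1 = out1, out2 = out2)
}

test_that("ancestral state is the outgroup-confirmed sister allele", {
  cols <- make_columns(target = c("A", "A", "A", "A"),
                       sister = c("G", "G", "G", "G"),
                       out1 = c("G", "A", "G", "-"),
                       out2 = c("G", "A", "N", "G"))
  # confirmed by both; unconfirmed; confirmed by out1 only; by out2 only
  expect_identical(infer_ancestral_state(cols), c("G", NA, "G", "G"))
  # missing sister is never inferable
  cols2 <- make_columns("A", "N", "A", "A")
  expect_identical(infer_ancestral_state(cols2), NA_character_)
})

test_that("masking removes missing-data columns and masked intervals", {
  cols <- make_columns(target = c("A", "N", "A", "A", "A"),
                       sister = c("C", "C", "-", "C", "C"),
                       out1 = c("C", "C", "C", "N", "C"),
                       out2 = c("C", "C", "C", "-", "C"))
  res <- apply_masks(cols)
  # target missing at pos 1, sister missing at pos 2, both outgroups at pos 3
  expect_identical(res$columns$pos0, c(0L, 4L))
  expect_identical(res$callable_length, 2L)
  # an exclusion mask drops its columns as well
  res2 <- apply_masks(cols, data.frame(chrom = "chr1", start0 = 0, end0 = 1))
  expect_identical(res2$columns$pos0, 4L)
  expect_error(apply_masks(cols, data.frame(chrom = "chr1", start0 = 5, end0 = 2)),
               "malformed")
})

test_that("calls carry the ancestral-substituted trinucleotide context", {
  # target TTG with ancestral C at the middle position, flanks A and G
  cols <- make_columns(target = c("A", "T", "G"),
                       sister = c("A", "C", "G"),
                       out1 = c("A", "C", "G"),
                       out2 = c("A", "C", "G"))
  m <- call_lineage_mutations(cols)
  expect_identical(nrow(m), 1L)
  expect_identical(m$anc, "C")
  expect_identical(m$der, "T")
  expect_identical(m$context, "ACG")
  # target equal to ancestral state yields no call
  cols_eq <- make_columns("A", "A", "A", "A")
  expect_identical(nrow(call_lineage_mutations(cols_eq)), 0L)
})

test_that("whole-sequence calling agrees with the per-column path", {
  cfg <- simulation_config(genome_length = 20000, seed = 77)
  sim <- simulate_dataset(cfg)
  ms <- call_mutations(sim$alignment)
  filt <- apply_masks(alignment_columns(sim$alignment))
  m2 <- call_lineage_mutations(filt$columns)
  expect_identical(ms$callable_length, filt$callable_length)
  expect_identical(ms$mutations$pos0, m2$pos0)
  expect_identical(ms$mutations$anc, m2$anc)
  expect_identical(ms$mutations$der, m2$der)
  expect_identical(ms$mutations$context, m2$context)
})

test_that("with mutation-free sister and outgroups, calling recovers the truth exactly", {
  cfg <- simulation_config(
    genome_length = 1e5, seed = 88,
    branch_rates = c(target = 2e-3, sister = 0, internal = 0,
                     outgroup1 = 0, outgroup2 = 0),
    a3g_event_rate = 20 / 1e5)
  sim <- simulate_dataset(cfg)
  ms <- call_mutations(sim$alignment)
  expect_identical(ms$mutations$pos0, sim$truth$pos0)
  expect_identical(ms$mutations$anc, sim$truth$anc)
  expect_identical(ms$mutations$der, sim$truth$der)
  # ancestral haplotype equals the simulated ancestor at every position
  expect_identical(ms$ancestral[[1]], sim$target_ancestor)
})

test_that("calling is strand-agnostic under reverse complement", {
  fx <- planted_fixture()
  ms <- call_mutations(fx$sim$alignment)
  ms_rc <- call_mutations(revcomp_alignment(fx$sim$alignment))
  L <- fx$sim$config$genome_length
  expect_identical(sort(as.integer(L - 1 - ms_rc$mutations$pos0)),
                   ms$mutations$pos0)
  o <- order(L - 1 - ms_rc$mutations$pos0)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  expect_identical(unname(comp[ms_rc$mutations$anc[o]]), ms$mutations$anc)
  expect_identical(unname(comp[ms_rc$mutations$der[o]]), ms$mutations$der)
})

test_that("background mutation calling recovers the truth at high rates", {
  fx <- planted_fixture()
  ms <- call_mutations(fx$sim$alignment, masks = fx$sim$annotations["repeat_mask"])
  truth <- fx$sim$truth
  # restrict truth to callable, non-masked sites
  callable <- rep(FALSE, fx$sim$config$genome_length)
  for (i in seq_len(nrow(ms$callable))) {
    callable[(ms$callable$start0[i] + 1):ms$callable$end0[i]] <- TRUE
  }
  tr <- truth[callable[truth$pos0 + 1], ]
  recovered <- tr$pos0 %in% ms$mutations$pos0
  expect_gt(mean(recovered), 0.95)
})

test_that("lineage partition follows the allele tracks", {
  muts <- data.frame(chrom = "chr1", pos0 = c(10L, 20L, 30L, 40L),
                     anc = "C", der = "T")
  tracks <- rbind(
    data.frame(chrom = "chr1", pos0 = c(10L, 20L, 30L, 40L), lineage = "modern",
               allele = c("T", "T", "C", "T")),
    data.frame(chrom = "chr1", pos0 = c(10L, 20L, 30L, 40L), lineage = "neandertal",
               allele = c("T", "C", "T", "T")),
    data.frame(chrom = "chr1", pos0 = c(10L, 20L, 30L), lineage = "denisovan",
               allele = c("T", "C", "C")))
  out <- partition_by_lineage(muts, tracks)
  # all carry; modern only; neandertal only; missing denisovan data
  expect_identical(out$lineage, c("common", "modern", "neandertal", "unassigned"))
  bad <- tracks
  bad$allele[1] <- "G"
  expect_error(partition_by_lineage(muts, bad), "consistency error")
})

test_that("simulated allele tracks reproduce the planted lineage assignment", {
  fx <- planted_fixture()
  truth <- fx$sim$truth
  out <- partition_by_lineage(truth, fx$sim$tracks)
  expect_identical(out$lineage, truth$lineage)
})
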