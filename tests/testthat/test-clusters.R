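# Cluster chaining, exclusion, typing, the negative-binomial P-value and the
# expected-count formulas.

muts_at <- function(pos0, anc = "C", chrom = "chr1") {
  data.frame(chrom = chrom, pos0 = as.integer(pos0),
             anc = rep_len(anc, length(pos0)),
             der = "T", lineage = "target",
             context = "NCN")
}

test_that("chaining joins consecutive mutations within the spacing limit", {
  cs <- detect_clusters(muts_at(c(100, 140, 190)))
  expect_identical(nrow(cs$clusters), 1L)
  expect_identical(cs$clusters$k, 3L)
  expect_identical(cs$clusters$span, 91)
  # a 51-bp gap breaks the chain
  cs2 <- detect_clusters(muts_at(c(100, 151)))
  expect_identical(nrow(cs2$clusters), 0L)
  # boundary: exactly 50 bp joins
  cs3 <- detect_clusters(muts_at(c(100, 150)))
  expect_identical(cs3$clusters$k, 2L)
  expect_error(detect_clusters(muts_at(c(5, 2))), "sorted")
  expect_error(detect_clusters(muts_at(c(5, 5))), "unique")
})

test_that("alternative spacings and the window mode behave as documented", {
  pos <- c(0, 60, 120, 500)
  expect_identical(nrow(detect_clusters(muts_at(pos), max_spacing = 50)$clusters), 0L)
  cs100 <- detect_clusters(muts_at(pos), max_spacing = 100)
  expect_identical(cs100$clusters$k, 3L)
  # window mode bounds the span, not the consecutive gap
  csw <- detect_clusters(muts_at(pos), max_spacing = 100, method = "window")
  expect_identical(csw$clusters$k, 2L)  # 0,60; 120 starts a new window
})

test_that("complex-mutation exclusion removes whole clusters at <=10 bp gaps", {
  cs <- detect_clusters(muts_at(c(100, 105, 140)))
  cs <- exclude_complex(cs)
  expect_identical(nrow(cs$clusters), 0L)
  expect_identical(nrow(cs$excluded), 1L)
  expect_true(all(is.na(cs$mutations$cluster)))
  # min gap 11 survives
  cs2 <- exclude_complex(detect_clusters(muts_at(c(100, 111, 150))))
  expect_identical(cs2$clusters$k, 3L)
})

test_that("cluster typing requires a shared ancestral state", {
  m <- rbind(muts_at(c(10, 20), anc = "C"),
             muts_at(c(300, 310), anc = c("C", "G")),
             muts_at(c(600, 620), anc = "A"))
  m <- m[order(m$pos0), ]
  cs <- classify_clusters(detect_clusters(m), callable_length = 10000)
  expect_identical(unname(cs$clusters$type), c("C", "N", "A"))
  # typing is invariant to within-cluster order of ancestral labels
  m2 <- rbind(muts_at(c(300, 310), anc = c("G", "C")))
  cs2 <- classify_clusters(detect_clusters(m2), callable_length = 10000)
  expect_identical(unname(cs2$clusters$type), "N")
})

test_that("the cluster P-value matches its oracles and closed form", {
  # k=2, x=2: single term pi^(k-1)
  expect_equal(cluster_pvalue(2, 2, 0.001), 0.001)
  # k=2 closed form 1-(1-pi)^(x-1)
  expect_equal(cluster_pvalue(2, 51, 0.001), 1 - 0.999^50, tolerance = 1e-12)
  # term-by-term summation oracle
  for (case in list(c(2, 51, 1e-3), c(3, 52, 1e-3), c(4, 30, 1e-2),
                    c(5, 100, 5e-3), c(2, 2, 0.5))) {
    expect_equal(cluster_pvalue(case[1], case[2], case[3]),
                 nb_pvalue_oracle(case[1], case[2], case[3]),
                 tolerance = 1e-12)
  }
  # monotone: nondecreasing in x, nonincreasing in k at fixed x
  p_x <- cluster_pvalue(3, 3:200, 0.001)
  expect_true(all(diff(p_x) >= 0))
  expect_true(all(diff(cluster_pvalue(2:6, 50, 0.01)) <= 0))
  # p -> 1 as x grows
  expect_equal(cluster_pvalue(3, 1e6, 0.001), 1, tolerance = 1e-6)
  expect_error(cluster_pvalue(1, 5, 0.01), "at least 2")
  expect_error(cluster_pvalue(3, 2, 0.01), "at least k")
  expect_error(cluster_pvalue(2, 5, 0), "strictly between")
})

test_that("chaining, exclusion and typing agree with the brute-force oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n <- 2000
    pos <- sort(sample.int(2e6, n))
    anc <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    m <- muts_at(pos, anc = anc)
    cs <- detect_clusters(m)
    oracle <- brute_cluster_oracle(pos)
    expect_identical(cs$mutations$cluster, oracle)
    # exclusion agrees too
    csx <- exclude_complex(cs)
    keep_oracle <- tapply(pos, oracle, function(p) all(diff(sort(p)) > 10))
    expected_kept <- sum(keep_oracle, na.rm = TRUE)
    expect_identical(nrow(csx$clusters), as.integer(expected_kept))
  }
})

test_that("planted events are recovered as coordinated clusters at low background", {
  cfg <- simulation_config(
    genome_length = 2e6, seed = 1234,
    branch_rates = c(target = 1e-4, sister = 1e-4, internal = 1e-3,
                     outgroup1 = 0.02, outgroup2 = 0.06),
    a3g_event_rate = 1e-4)
  sim <- simulate_dataset(cfg)
  ms <- call_mutations(sim$alignment)
  cs <- classify_clusters(exclude_complex(detect_clusters(ms)))
  ctype <- a3gclust:::mutation_cluster_types(cs)
  cg_cluster <- cs$mutations$cluster
  cg_cluster[is.na(ctype) | !(ctype %in% c("C", "G"))] <- NA
  cl_of <- stats::setNames(cg_cluster, cs$mutations$pos0)
  truth <- sim$truth[sim$truth$event_class == "a3g", ]
  recovered <- vapply(split(truth$pos0, truth$event_id), function(p) {
    cl <- cl_of[as.character(p)]
    cl <- cl[!is.na(cl)]
    length(cl) >= 2 && any(table(cl) >= 2)
  }, logical(1))
  expect_gt(length(recovered), 150)
  expect_gte(mean(recovered), 0.95)
})

test_that("P-value filtering is monotone in the threshold", {
  fx <- planted_fixture()
  cs <- fx$cs
  s1 <- filter_by_pvalue(cs, 0.001)$clusters$cluster
  s2 <- filter_by_pvalue(cs, 0.01)$clusters$cluster
  expect_true(all(s1 %in% s2))
  expect_identical(filter_by_pvalue(cs, 1)$clusters$cluster, cs$clusters$cluster)
  expect_error(filter_by_pvalue(cs, 0), "0, 1")
  expect_error(filter_by_pvalue(cs, 1.5), "0, 1")
})

test_that("expected-count formulas match their closed forms", {
  n_i <- c("2" = 10, "3" = 4)
  expect_equal(expected_same_ancestor_clusters(n_i, 1), 14)
  expect_equal(expected_same_ancestor_clusters(c("2" = 10), 0.25), 0.625)
  expect_equal(expected_a3g_clusters(n_i, 0), 0)
  expect_equal(expected_a3g_clusters(c("2" = 10), 0.5), 7.5)
  # the printed binomial sum equals the 1-(1-p)^i closed form
  p <- 0.123
  for (i in 2:10) {
    j <- 1:i
    binom_sum <- sum(choose(i, j) * p^j * (1 - p)^(i - j))
    expect_equal(unname(expected_a3g_clusters(stats::setNames(1, i), p)),
                 binom_sum, tolerance = 1e-12)
  }
})

test_that("A3G cluster definition requires a CCC (or GGG) member mutation", {
  # genome with one CCC cluster, one C cluster without CCC, one GGG cluster
  seq <- paste(rep("A", 400), collapse = "")
  substr(seq, 99, 101) <- "CCC"    # pos0 98..100, CCC mutated at pos0 100
  substr(seq, 131, 131) <- "C"     # second C mutation, context ACA at pos0 130
  substr(seq, 199, 201) <- "ACA"   # C at pos0 199 (TCA-like context)
  substr(seq, 231, 231) <- "C"     # pos0 230
  substr(seq, 299, 301) <- "GGG"   # G cluster; mutated G at pos0 298
  substr(seq, 331, 331) <- "G"     # pos0 330
  ms <- toy_mutation_set(seq, pos0 = c(100L, 130L, 199L, 230L, 298L, 330L))
  cs <- classify_clusters(detect_clusters(ms), callable_length = 400)
  expect_identical(unname(cs$clusters$type), c("C", "C", "G"))
  a3g <- define_a3g_clusters(cs)
  expect_identical(sort(a3g$clusters$start0), c(100, 298))
  expect_identical(sort(a3g$mutations$pos0), c(100L, 130L, 298L, 330L))
})
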