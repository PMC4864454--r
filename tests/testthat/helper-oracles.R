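# Independent oracles used to verify the implementation. These deliberately
# avoid the package's own code paths: term-by-term summation for the
# negative-binomial CDF, all-pairs graph components for chaining,
# log-choose hypergeometric tails for Fisher tests, and naive
# position-by-position scans for motif counting.

# Term-by-term evaluation of p = sum_{j=0}^{x-k} C(k-2+j, j) (1-pi)^j pi^(k-1)
nb_pvalue_oracle <- function(k, x, pi) {
  j <- 0:(x - k)
  sum(choose(k - 2 + j, j) * (1 - pi)^j * pi^(k - 1))
}

# Brute-force clustering: connect every pair of positions within max_spacing
# and take connected components (equivalent to transitive chaining).
brute_cluster_oracle <- function(pos0, max_spacing = 50, min_size = 2) {
  n <- length(pos0)
  edges <- integer(0)
  block <- 500L
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d <- abs(outer(pos0[s:e], pos0, "-")) <= max_spacing
    idx <- which(d, arr.ind = TRUE)
    idx[, 1] <- idx[, 1] + s - 1L
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    edges <- c(edges, t(idx))
  }
  g <- igraph::make_graph(edges, n = n, directed = FALSE)
  comp <- igraph::components(g)$membership
  sizes <- table(comp)
  keep <- comp %in% as.integer(names(sizes)[sizes >= min_size])
  cl <- rep(NA_integer_, n)
  cl[keep] <- match(comp[keep], sort(unique(comp[keep])))
  cl
}

# One-tailed (greater) Fisher p-value by direct hypergeometric enumeration.
fisher_greater_oracle <- function(a, b, c, d) {
  m <- a + b       # row 1 total
  n2 <- c + d      # row 2 total
  kk <- a + c      # column 1 total
  t_vals <- max(0, kk - n2):min(m, kk)
  logp <- lchoose(m, t_vals) + lchoose(n2, kk - t_vals) - lchoose(m + n2, kk)
  sum(exp(logp[t_vals >= a]))
}

# Naive scan: count motif occurrences (mutated-base positions, both strands)
# by checking the IUPAC pattern at every offset.
naive_motif_count <- function(seq, pattern, mutated_index) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", W = c("A", "T"),
               R = c("A", "G"), Y = c("C", "T"), N = c("A", "C", "G", "T"))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(seq, "")[[1]]
  pl <- strsplit(pattern, "")[[1]]
  Lp <- length(pl)
  n <- 0L
  for (s in seq_len(length(ch) - Lp + 1)) {
    if (all(mapply(function(cc, pp) cc %in% sets[[pp]], ch[s:(s + Lp - 1)], pl))) {
      n <- n + 1L
    }
    # minus strand: reverse complement of the window matches the pattern
    win_rc <- rev(unname(comp[ch[s:(s + Lp - 1)]]))
    if (all(mapply(function(cc, pp) cc %in% sets[[pp]], win_rc, pl))) {
      n <- n + 1L
    }
  }
  n
}

# Brute-force interval overlap: is each position inside any interval?
naive_in_region <- function(pos0, regions) {
  vapply(pos0, function(p) {
    any(p >= regions$start0 & p < regions$end0)
  }, logical(1))
}

random_dna <- function(L, gc = 0.41) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
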