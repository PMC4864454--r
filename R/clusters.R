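# Cluster detection and scoring: chain nearby mutations, exclude potential
# complex mutations, classify clusters by shared ancestral nucleotide, and
# score each cluster with a negative-binomial P-value.

#' Chain mutations into clusters
#'
#' A cluster is a maximal run of at least `min_size` mutations on one
#' chromosome in which every consecutive pair is separated by at most
#' `max_spacing` bp (transitive chaining; distance is the absolute difference
#' of 0-based positions). An alternative `"window"` mode instead grows a
#' cluster greedily while the total span from its first mutation stays within
#' `max_spacing`, for sensitivity analyses.
#'
#' @param x a `mutation_set` or a mutation data frame (chrom, pos0, anc, ...),
#'   sorted by chromosome and position with unique positions.
#' @param max_spacing maximum spacing between consecutive cluster members
#'   (bp); 50 by default, with 100/300/1000 as supported alternatives.
#' @param min_size minimum number of mutations per cluster.
#' @param method `"chain"` (consecutive-pair distance) or `"window"`
#'   (all members within `max_spacing` of the cluster's first mutation).
#' @return object of class `cluster_set`: list with `mutations` (the input
#'   table plus a `cluster` id column, NA for unclustered), `clusters`
#'   (per-cluster table: cluster, chrom, start0, end0, k, span), the chaining
#'   `params`, and `source` (the mutation_set, when one was given).
#' @export
detect_clusters <- function(x, max_spacing = 50, min_size = 2,
                            method = c("chain", "window")) {
  method <- match.arg(method)
  ms <- NULL
  if (inherits(x, "mutation_set")) {
    ms <- x
    muts <- x$mutations
  } else {
    muts <- x
  }
  if (nrow(muts) > 1) {
    o <- order(muts$chrom, muts$pos0)
    if (any(o != seq_len(nrow(muts)))) {
      stop("mutations must be sorted by (chrom, pos0)")
    }
    same <- muts$chrom[-1] == muts$chrom[-nrow(muts)]
    if (any(same & diff(muts$pos0) == 0)) {
      stop("mutations must have unique positions")
    }
  }
  cl <- integer(nrow(muts))
  if (nrow(muts)) {
    if (method == "chain") {
      gap_new <- if (nrow(muts) == 1) logical(0) else {
        muts$chrom[-1] != muts$chrom[-nrow(muts)] | diff(muts$pos0) > max_spacing
      }
      cl <- cumsum(c(TRUE, gap_new))
    } else {
      cl <- integer(nrow(muts))
      cid <- 1L
      anchor <- muts$pos0[1]
      cl[1] <- cid
      for (i in seq_len(nrow(muts))[-1]) {
        if (muts$chrom[i] != muts$chrom[i - 1] ||
            muts$pos0[i] - anchor > max_spacing) {
          cid <- cid + 1L
          anchor <- muts$pos0[i]
        }
        cl[i] <- cid
      }
    }
    sizes <- tabulate(cl)
    keep <- sizes[cl] >= min_size
    cl[!keep] <- NA_integer_
    # renumber surviving clusters consecutively
    cl <- match(cl, sort(unique(cl[!is.na(cl)])))
  }
  muts$cluster <- cl
  clusters <- summarize_clusters(muts)
  structure(list(mutations = muts, clusters = clusters,
                 params = list(max_spacing = max_spacing, min_size = min_size,
                               method = method),
                 source = ms),
            class = "cluster_set")
}

summarize_clusters <- function(muts) {
  cm <- muts[!is.na(muts$cluster), , drop = FALSE]
  if (!nrow(cm)) {
    return(data.frame(cluster = integer(0), chrom = character(0),
                      start0 = integer(0), end0 = integer(0),
                      k = integer(0), span = integer(0)))
  }
  sp <- split(seq_len(nrow(cm)), cm$cluster)
  data.frame(
    cluster = as.integer(names(sp)),
    chrom = vapply(sp, function(i) cm$chrom[i[1]], character(1)),
    start0 = vapply(sp, function(i) min(cm$pos0[i]), numeric(1)),
    end0 = vapply(sp, function(i) max(cm$pos0[i]), numeric(1)),
    k = lengths(sp),
    span = vapply(sp, function(i) max(cm$pos0[i]) - min(cm$pos0[i]) + 1, numeric(1)),
    row.names = NULL)
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("cluster_set: %d clusters (%d mutations clustered of %d), max_spacing=%d\n",
              nrow(x$clusters), sum(!is.na(x$mutations$cluster)),
              nrow(x$mutations), x$params$max_spacing))
  if (!is.null(x$clusters$type)) {
    print(table(type = x$clusters$type))
  }
  invisible(x)
}

#' Remove clusters containing potential complex mutations
#'
#' A multi-nucleotide (complex) mutation event can mimic a cluster; any
#' cluster containing a consecutive pair of mutations separated by
#' `min_spacing` bp or less is therefore removed entirely. Removed clusters
#' are retained in the `excluded` element for audit.
#'
#' @param cs a `cluster_set`.
#' @param min_spacing complex-mutation distance threshold (bp).
#' @return the filtered `cluster_set` (excluded cluster table in
#'   `$excluded`; their member mutations are marked unclustered).
#' @export
exclude_complex <- function(cs, min_spacing = 10) {
  muts <- cs$mutations
  cm <- muts[!is.na(muts$cluster), , drop = FALSE]
  bad_ids <- as.integer(names(which(
    vapply(split(cm$pos0, cm$cluster), function(p) any(diff(sort(p)) <= min_spacing),
           logical(1)))))
  cs$excluded <- cs$clusters[cs$clusters$cluster %in% bad_ids, , drop = FALSE]
  cs$clusters <- cs$clusters[!cs$clusters$cluster %in% bad_ids, , drop = FALSE]
  cs$mutations$cluster[cs$mutations$cluster %in% bad_ids] <- NA_integer_
  cs$params$min_spacing_complex <- min_spacing
  cs
}

#' Classify clusters by shared ancestral nucleotide and score them
#'
#' Clusters whose member mutations all share the same ancestral base are
#' typed by that base (e.g. C-coordinated); clusters mixing ancestral states
#' are typed `N` and excluded from coordinated-cluster statistics (but never
#' silently dropped). Also computes the cluster-size histogram `n_i`, the
#' genome-wide per-bp mutation probability `pi` (total mutations over
#' callable length), and the negative-binomial P-value of every cluster.
#'
#' @param cs a `cluster_set`.
#' @param callable_length callable genome length (defaults to the source
#'   mutation_set's).
#' @return the `cluster_set` with `type` and `p_value` columns on
#'   `$clusters`, plus `$n_i` (all clusters), `$n_i_by_type`, and `$pi`.
#' @export
classify_clusters <- function(cs, callable_length = NULL) {
  if (is.null(callable_length)) {
    if (is.null(cs$source)) stop("callable_length required when no source mutation_set")
    callable_length <- cs$source$callable_length
  }
  muts <- cs$mutations
  cm <- muts[!is.na(muts$cluster), , drop = FALSE]
  type <- vapply(split(cm$anc, cm$cluster), function(a) {
    if (length(unique(a)) == 1) a[1] else "N"
  }, character(1))
  cs$clusters$type <- unname(type[as.character(cs$clusters$cluster)])
  pi_hat <- nrow(muts) / callable_length
  if (pi_hat <= 0 || pi_hat >= 1) stop("mutation probability pi outside (0,1)")
  cs$pi <- pi_hat
  cs$callable_length <- callable_length
  cs$clusters$p_value <- cluster_pvalue(cs$clusters$k, cs$clusters$span, pi_hat)
  ks <- cs$clusters$k
  cs$n_i <- if (length(ks)) table(factor(ks, levels = 2:max(ks))) else table(integer(0))
  cs$n_i_by_type <- tapply(cs$clusters$k, cs$clusters$type,
                           function(k) table(factor(k, levels = 2:max(c(k, 2)))))
  cs
}

#' Negative-binomial cluster P-value
#'
#' The probability of observing `k - 1` further mutations within `x - 1` bp
#' of the first, when mutations hit each position independently with
#' probability `pi`:
#' \deqn{p = \sum_{j=0}^{x-k} \binom{k-2+j}{j} (1-\pi)^j \pi^{k-1},}
#' the lower CDF of a negative binomial with `k - 1` successes of probability
#' `pi`, evaluated at `x - k` failures. For `k = 2` this reduces to the
#' closed form `1 - (1 - pi)^(x-1)`.
#'
#' @param k number of mutations in the cluster (>= 2); vectorized.
#' @param x cluster span in bp (last - first + 1, >= k); vectorized.
#' @param pi genome-wide per-bp mutation probability, in (0, 1).
#' @return P-values in (0, 1].
#' @export
cluster_pvalue <- function(k, x, pi) {
  if (any(k < 2)) stop("cluster size k must be at least 2")
  if (any(x < k)) stop("cluster span x must be at least k")
  if (any(pi <= 0 | pi >= 1)) stop("pi must lie strictly between 0 and 1")
  stats::pnbinom(x - k, size = k - 1, prob = pi)
}

#' Filter clusters by P-value threshold
#'
#' @param cs a classified `cluster_set`.
#' @param threshold keep clusters with `p_value <= threshold`; must lie in
#'   (0, 1].
#' @return the filtered `cluster_set` (threshold recorded in `$params`).
#' @export
filter_by_pvalue <- function(cs, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must lie in (0, 1]")
  }
  if (is.null(cs$clusters$p_value)) stop("run classify_clusters() first")
  keep_ids <- cs$clusters$cluster[cs$clusters$p_value <= threshold]
  cs$clusters <- cs$clusters[cs$clusters$cluster %in% keep_ids, , drop = FALSE]
  cs$mutations$cluster[!(cs$mutations$cluster %in% keep_ids)] <- NA_integer_
  cs$params$p_threshold <- threshold
  cs
}

#' Expected number of same-ancestor (coordinated) clusters
#'
#' Under independent mutations, the chance that all `i` members of a cluster
#' share one particular ancestral state is `p^i`, so the expected number of
#' coordinated clusters of that state is `sum_i N_i * p^i`.
#'
#' @param n_i cluster-size histogram (named vector/table, names = sizes).
#' @param p prevalence of mutations from the ancestral state in question.
#' @return expected coordinated-cluster count.
#' @export
expected_same_ancestor_clusters <- function(n_i, p) {
  assert_probability(p, "p")
  i <- as.numeric(names(n_i))
  sum(as.numeric(n_i) * p^i)
}

#' Expected number of clusters containing at least one motif mutation
#'
#' With per-mutation motif probability `p`, a cluster of size `i` contains at
#' least one motif mutation with probability `1 - (1-p)^i` (the binomial sum
#' over j >= 1 hits), giving `sum_i N_i * (1 - (1-p)^i)`.
#'
#' @param n_i cluster-size histogram (named vector/table, names = sizes).
#' @param p_motif probability that a clustered mutation falls in the motif.
#' @return expected count of motif-containing clusters.
#' @export
expected_a3g_clusters <- function(n_i, p_motif) {
  assert_probability(p_motif, "p_motif")
  i <- as.numeric(names(n_i))
  sum(as.numeric(n_i) * (1 - (1 - p_motif)^i))
}

#' Select A3G clusters: coordinated clusters with a CCC (GGG) mutation
#'
#' A3G clusters are C-coordinated clusters containing at least one mutation
#' at the mutated position of a plus-strand CCC context, together with
#' G-coordinated clusters containing at least one reverse-complement (GGG)
#' match. The union of their member mutations is the A3G-induced set.
#'
#' @param cs a classified (optionally P-value-filtered) `cluster_set`.
#' @param motif the motif to require; defaults to A3G CCC (mutated 3' C).
#' @return list with `clusters` (the qualifying cluster table),
#'   `mutations` (all member mutations of qualifying clusters) and
#'   `cluster_set` (the subsetted cluster_set).
#' @export
define_a3g_clusters <- function(cs, motif = motif_ccc()) {
  if (is.null(cs$clusters$type)) stop("run classify_clusters() first")
  m <- motif_match_flags(cs, motif)
  muts <- cs$mutations
  cl_ids <- unique(muts$cluster[!is.na(muts$cluster) & m])
  sel <- cs$clusters$cluster %in% cl_ids &
    cs$clusters$type %in% c("C", "G")
  keep_ids <- cs$clusters$cluster[sel]
  out_cs <- cs
  out_cs$clusters <- cs$clusters[sel, , drop = FALSE]
  out_cs$mutations$cluster[!(out_cs$mutations$cluster %in% keep_ids)] <- NA_integer_
  list(clusters = out_cs$clusters,
       mutations = out_cs$mutations[!is.na(out_cs$mutations$cluster), , drop = FALSE],
       cluster_set = out_cs)
}
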