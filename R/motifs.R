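# Deaminase motif enrichment within coordinated mutation clusters: signal
# fractions, four background models, exact tests, the 48-trinucleotide scan,
# CpG controls, and the enrichment-versus-confidence correlation.

#' Define a deaminase sequence motif
#'
#' @param pattern IUPAC string of length 2-4 using A, C, G, T, W, R, Y, N.
#' @param mutated_index 0-based position of the deaminated cytosine within
#'   the pattern; that pattern position must be exactly `C`.
#' @param label display label.
#' @return object of class `motif`.
#' @export
motif <- function(pattern, mutated_index, label = pattern) {
  pattern <- toupper(pattern)
  chars <- seq_chars(pattern)
  if (nchar(pattern) < 2 || nchar(pattern) > 4) {
    stop("motif pattern must have length 2-4")
  }
  if (!all(chars %in% c("A", "C", "G", "T", "W", "R", "Y", "N"))) {
    stop("motif pattern may only use A, C, G, T, W, R, Y, N")
  }
  if (mutated_index < 0 || mutated_index >= nchar(pattern)) {
    stop("mutated_index outside pattern")
  }
  if (chars[mutated_index + 1] != "C") {
    stop("the mutated position of a motif must be C")
  }
  structure(list(pattern = pattern, mutated_index = as.integer(mutated_index),
                 label = label),
            class = "motif")
}

#' @export
print.motif <- function(x, ...) {
  cat(sprintf("motif %s: %s (mutated position %d)\n", x$label, x$pattern,
              x$mutated_index))
  invisible(x)
}

#' A3G stringent motif CCC (mutated 3' cytosine)
#' @return a [motif].
#' @export
motif_ccc <- function() motif("CCC", 2, "A3G-CCC")

#' A3G lenient motif CC (mutated 3' cytosine)
#' @return a [motif].
#' @export
motif_cc <- function() motif("CC", 1, "A3G-CC")

#' Standard APOBEC/AID motif panel
#'
#' Mutated positions follow the deaminase signature literature: CC and CCC
#' mutate the 3' C (A3G), TC and TCW the C after T (A3B), TTC the 3' C
#' (A3F), WRC the 3' C (AID). The mouse A3 motif TYC (3' C) is included as
#' a negative-control entry for non-primate analyses.
#'
#' @param include_mouse include the mouse TYC motif.
#' @return named list of [motif] objects.
#' @export
a3g_motif_panel <- function(include_mouse = FALSE) {
  panel <- list(
    `A3G-CC` = motif("CC", 1, "A3G-CC"),
    `A3G-CCC` = motif("CCC", 2, "A3G-CCC"),
    `A3B-TC` = motif("TC", 1, "A3B-TC"),
    `A3B-TCW` = motif("TCW", 1, "A3B-TCW"),
    `A3F-TTC` = motif("TTC", 2, "A3F-TTC"),
    `AID-WRC` = motif("WRC", 2, "AID-WRC"))
  if (include_mouse) panel$`mA3-TYC` <- motif("TYC", 2, "mA3-TYC")
  panel
}

# Match a motif at given 0-based positions of a chromosome character vector.
# strand "-" tests the reverse-complement pattern at the mirrored register.
match_at_positions <- function(ch, pos0, motif, strand = "+") {
  pat <- motif$pattern
  m <- motif$mutated_index
  if (strand == "-") {
    pat <- revcomp(pat)
    m <- nchar(pat) - 1L - m
  }
  pl <- seq_chars(pat)
  Lp <- length(pl)
  L <- length(ch)
  if (!length(pos0)) return(logical(0))
  start0 <- pos0 - m
  res <- start0 >= 0 & start0 + Lp <= L
  for (j in seq_len(Lp)) {
    idx <- ifelse(res, start0 + j, 1L)  # 1-based index, guarded
    res <- res & ch[idx] %in% IUPAC_SETS[[pl[j]]]
  }
  res
}

#' Match a motif against context windows
#'
#' Windows must be odd-length strings centered on the mutated base, with
#' ancestral alleles substituted. On the plus strand the pattern is matched
#' with the window center at `mutated_index`; on the minus strand the
#' reverse-complement pattern is matched at the mirrored index.
#'
#' @param context_window character vector of odd-length windows.
#' @param motif a [motif].
#' @param strand "+" or "-".
#' @return logical vector.
#' @export
match_motif <- function(context_window, motif, strand = c("+", "-")) {
  strand <- match.arg(strand)
  w <- nchar(context_window)
  if (length(unique(w)) > 1) stop("context windows must share one length")
  w <- w[1]
  if (w %% 2 == 0) stop("context windows must be odd-length (centered)")
  need_left <- if (strand == "+") motif$mutated_index else
    nchar(motif$pattern) - 1L - motif$mutated_index
  need_right <- nchar(motif$pattern) - 1L - need_left
  half <- (w - 1L) / 2L
  if (half < need_left || half < need_right) {
    stop("context window shorter than motif pattern")
  }
  vapply(context_window, function(win) {
    match_at_positions(seq_chars(win), half, motif, strand)
  }, logical(1), USE.NAMES = FALSE)
}

# Cluster type per mutation row (NA for unclustered mutations).
mutation_cluster_types <- function(cs) {
  type_of <- stats::setNames(cs$clusters$type, cs$clusters$cluster)
  unname(type_of[as.character(cs$mutations$cluster)])
}

cs_source <- function(cs) {
  if (is.null(cs$source)) {
    stop("this cluster_set does not carry its mutation_set; rebuild it with detect_clusters(<mutation_set>, ...)")
  }
  cs$source
}

# Motif match flag per mutation row: plus strand inside C-coordinated
# clusters, minus strand (reverse complement) inside G-coordinated clusters.
motif_match_flags <- function(cs, motif) {
  ms <- cs_source(cs)
  muts <- cs$mutations
  ctype <- mutation_cluster_types(cs)
  flags <- logical(nrow(muts))
  for (chrom in unique(muts$chrom)) {
    ch <- seq_chars(ms$ancestral[[chrom]])
    i <- which(muts$chrom == chrom & !is.na(ctype) & ctype == "C")
    flags[i] <- match_at_positions(ch, muts$pos0[i], motif, "+")
    i <- which(muts$chrom == chrom & !is.na(ctype) & ctype == "G")
    flags[i] <- match_at_positions(ch, muts$pos0[i], motif, "-")
  }
  flags
}

# Is the mutated base part of a CpG on its mutated strand? For ancestral C
# (plus strand) that means a following G; for ancestral G (minus strand),
# a preceding C.
mutated_base_in_cpg <- function(ms, chrom, pos0, strand) {
  ch <- seq_chars(ms$ancestral[[chrom]])
  L <- length(ch)
  ifelse(strand == "+",
         pos0 + 2L <= L & ch[pmin(pos0 + 2L, L)] == "G",
         pos0 >= 1L & ch[pmax(pos0, 1L)] == "C")
}

#' Motif signal within coordinated clusters
#'
#' The fraction of clustered mutations falling at the mutated position of the
#' motif, out of all mutations in C- and G-coordinated clusters (C-clusters
#' matched on the plus strand, G-clusters on the minus strand via the
#' reverse-complement pattern).
#'
#' @param cs a classified `cluster_set` built from a `mutation_set`.
#' @param motif a [motif].
#' @param cpg_filter drop mutations whose mutated base lies in a CpG on its
#'   strand (numerator and denominator).
#' @param exclude_cccg drop motif matches whose mutated C is followed by G
#'   (numerator only); used to separate deaminase signal from CpG
#'   deamination at overlapping contexts.
#' @return list with `ratio`, `n_match`, `n_total`.
#' @export
motif_signal <- function(cs, motif, cpg_filter = FALSE, exclude_cccg = FALSE) {
  ms <- cs_source(cs)
  muts <- cs$mutations
  ctype <- mutation_cluster_types(cs)
  in_cg <- !is.na(ctype) & ctype %in% c("C", "G")
  strand <- ifelse(ctype == "C", "+", "-")
  flags <- motif_match_flags(cs, motif)
  if (cpg_filter || exclude_cccg) {
    cpg <- rep(FALSE, nrow(muts))
    for (chrom in unique(muts$chrom)) {
      i <- which(muts$chrom == chrom & in_cg)
      cpg[i] <- mutated_base_in_cpg(ms, chrom, muts$pos0[i], strand[i])
    }
    if (cpg_filter) in_cg <- in_cg & !cpg
    if (exclude_cccg) flags <- flags & !cpg
  }
  n_total <- sum(in_cg)
  if (n_total == 0) stop("undefined signal: no mutations in C- or G-coordinated clusters")
  n_match <- sum(flags & in_cg)
  list(ratio = n_match / n_total, n_match = n_match, n_total = n_total)
}

# 0-based genomic positions of the motif's mutated base, per strand.
genome_motif_positions <- function(seq_string, motif) {
  subj <- Biostrings::DNAString(seq_string)
  Lp <- nchar(motif$pattern)
  m <- motif$mutated_index
  plus <- Biostrings::start(
    Biostrings::matchPattern(motif$pattern, subj, fixed = FALSE)) - 1L + m
  minus <- Biostrings::start(
    Biostrings::matchPattern(revcomp(motif$pattern), subj, fixed = FALSE)) -
    1L + (Lp - 1L - m)
  list(plus = plus, minus = minus)
}

#' Genomic background: motif frequency among genomic C/G positions
#'
#' The number of motif occurrences in the genome (both strands: pattern with
#' its mutated C, and reverse complement with the mirrored G) over the number
#' of C plus G nucleotides, matching the strand pooling of [motif_signal()].
#'
#' @param genome a `mutation_set` (its ancestral haplotype is used) or a
#'   character scalar / named list of chromosome sequences.
#' @param motif a [motif].
#' @param cpg_mask exclude CpG cytosines (C followed by G) and CpG guanines
#'   (G preceded by C) from both the motif occurrences and the base counts.
#' @param exclude_cccg exclude motif occurrences whose mutated C is followed
#'   by G (numerator only).
#' @return list with `ratio`, `n_motif`, `n_base`.
#' @export
genomic_background <- function(genome, motif, cpg_mask = FALSE,
                               exclude_cccg = FALSE) {
  seqs <- genome_sequences(genome)
  n_motif <- 0
  n_base <- 0
  for (s in seqs) {
    ch <- seq_chars(s)
    L <- length(ch)
    if (L == 0) stop("empty genome")
    cpg_c <- c(ch[-L] == "C" & ch[-1] == "G", FALSE)  # C of a CpG
    cpg_g <- c(FALSE, ch[-L] == "C" & ch[-1] == "G")  # G of a CpG
    pos <- genome_motif_positions(s, motif)
    plus <- pos$plus
    minus <- pos$minus
    if (cpg_mask || exclude_cccg) {
      plus <- plus[!cpg_c[plus + 1L]]
      minus <- minus[!cpg_g[minus + 1L]]
    }
    n_motif <- n_motif + length(plus) + length(minus)
    if (cpg_mask) {
      n_base <- n_base + sum(ch == "C" & !cpg_c) + sum(ch == "G" & !cpg_g)
    } else {
      n_base <- n_base + sum(ch == "C") + sum(ch == "G")
    }
  }
  if (n_base == 0) stop("genome contains no C or G nucleotides")
  list(ratio = n_motif / n_base, n_motif = n_motif, n_base = n_base)
}

genome_sequences <- function(genome) {
  if (inherits(genome, "mutation_set")) return(genome$ancestral)
  if (inherits(genome, "cluster_set")) return(cs_source(genome)$ancestral)
  if (is.character(genome)) return(as.list(genome))
  if (is.list(genome)) return(genome)
  stop("cannot interpret 'genome'")
}

#' Randomized-mutation background
#'
#' Generates `n_sets` randomized copies of the mutation set: every mutation
#' is re-placed uniformly at a callable position (on its own chromosome,
#' and by default at a position carrying its ancestral base, so that
#' signal/background ratios stay defined per ancestral state). Each
#' randomized set is re-clustered and filtered with the observed set's
#' parameters, and the motif fraction among its clustered C/G mutations is
#' computed; the background is the mean over sets.
#'
#' @param cs a classified `cluster_set`.
#' @param motif a [motif].
#' @param n_sets number of randomized sets.
#' @param seed optional seed.
#' @param base_matched re-place mutations on positions of the same ancestral
#'   base (default); if `FALSE`, placement is unconstrained within callable
#'   regions and the ancestral state is re-read from the genome.
#' @return list with `ratio` (mean over informative sets), `n_motif`,
#'   `n_base` (counts pooled over sets), `per_set` ratios.
#' @export
random_mutation_background <- function(cs, motif, n_sets = 100, seed = NULL,
                                       base_matched = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  ms <- cs_source(cs)
  muts <- ms$mutations
  pools <- callable_base_pools(ms, if (base_matched) unique(muts$anc) else NULL)
  per_set <- numeric(n_sets)
  tot_match <- 0
  tot_all <- 0
  for (r in seq_len(n_sets)) {
    rnd <- randomize_mutations(muts, pools, base_matched, ms)
    rcs <- recluster_like(cs, rnd, ms)
    counts <- clustered_motif_counts(rcs, ms, motif)
    per_set[r] <- if (counts$n_total > 0) counts$n_match / counts$n_total else NA_real_
    tot_match <- tot_match + counts$n_match
    tot_all <- tot_all + counts$n_total
  }
  if (all(is.na(per_set))) {
    stop("randomized sets produced no coordinated clusters; background undefined")
  }
  list(ratio = mean(per_set, na.rm = TRUE), n_motif = tot_match,
       n_base = tot_all, per_set = per_set)
}

# Positions (0-based) of each ancestral base within callable regions.
callable_base_pools <- function(ms, bases) {
  pools <- list()
  for (chrom in names(ms$ancestral)) {
    ch <- seq_chars(ms$ancestral[[chrom]])
    keep <- interval_mask(ms$callable[ms$callable$chrom == chrom, , drop = FALSE],
                          length(ch))
    if (is.null(bases)) {
      pools[[chrom]] <- list(ALL = which(keep) - 1L)
    } else {
      pools[[chrom]] <- lapply(stats::setNames(bases, bases), function(b) {
        which(keep & ch == b) - 1L
      })
    }
  }
  pools
}

randomize_mutations <- function(muts, pools, base_matched, ms) {
  out <- muts
  for (chrom in unique(muts$chrom)) {
    sel <- muts$chrom == chrom
    if (base_matched) {
      for (b in unique(muts$anc[sel])) {
        i <- which(sel & muts$anc == b)
        pool <- pools[[chrom]][[b]]
        if (length(pool) < length(i)) {
          stop(sprintf("insufficient matching positions for base %s on %s", b, chrom))
        }
        out$pos0[i] <- sample(pool, length(i))
      }
    } else {
      i <- which(sel)
      pool <- pools[[chrom]][["ALL"]]
      if (length(pool) < length(i)) stop("insufficient callable positions")
      out$pos0[i] <- sample(pool, length(i))
      ch <- seq_chars(ms$ancestral[[chrom]])
      out$anc[i] <- ch[out$pos0[i] + 1L]
    }
  }
  out <- out[order(out$chrom, out$pos0), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Re-run chaining/exclusion/classification/threshold with the parameters of
# an observed cluster_set on a new mutation table.
recluster_like <- function(cs, muts, ms) {
  muts$cluster <- NULL
  rcs <- detect_clusters(muts, max_spacing = cs$params$max_spacing,
                         min_size = cs$params$min_size,
                         method = cs$params$method)
  if (!is.null(cs$params$min_spacing_complex)) {
    rcs <- exclude_complex(rcs, cs$params$min_spacing_complex)
  }
  rcs <- classify_clusters(rcs, callable_length = ms$callable_length)
  if (!is.null(cs$params$p_threshold)) {
    rcs <- filter_by_pvalue(rcs, cs$params$p_threshold)
  }
  rcs$source <- ms
  rcs
}

clustered_motif_counts <- function(rcs, ms, motif) {
  ctype <- mutation_cluster_types(rcs)
  in_cg <- !is.na(ctype) & ctype %in% c("C", "G")
  if (!any(in_cg)) return(list(n_match = 0, n_total = 0))
  flags <- motif_match_flags(rcs, motif)
  list(n_match = sum(flags & in_cg), n_total = sum(in_cg))
}

#' Randomized-cluster background
#'
#' Each replicate relocates every observed C/G-coordinated cluster to a
#' uniform random locus on its chromosome, preserving cluster length, the
#' member mutations' offsets from the cluster start, and their strand (C
#' clusters stay plus-strand, G clusters minus). The motif fraction is then
#' computed from the genomic contexts at the relocated positions: positions
#' carrying the strand's ancestral base form the denominator and motif
#' matches the numerator.
#'
#' @inheritParams random_mutation_background
#' @return list with `ratio`, `n_motif`, `n_base`, `per_set`.
#' @export
random_cluster_background <- function(cs, motif, n_sets = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ms <- cs_source(cs)
  cl <- cs$clusters[cs$clusters$type %in% c("C", "G"), , drop = FALSE]
  if (!nrow(cl)) stop("no coordinated clusters to relocate")
  muts <- cs$mutations
  chars <- lapply(ms$ancestral, seq_chars)
  items <- lapply(seq_len(nrow(cl)), function(i) {
    mem <- muts[!is.na(muts$cluster) & muts$cluster == cl$cluster[i], , drop = FALSE]
    list(chrom = cl$chrom[i],
         offsets = mem$pos0 - cl$start0[i],
         span = cl$span[i],
         strand = if (cl$type[i] == "C") "+" else "-")
  })
  per_set <- numeric(n_sets)
  tot_match <- 0
  tot_base <- 0
  for (r in seq_len(n_sets)) {
    n_match <- 0
    n_base <- 0
    for (it in items) {
      ch <- chars[[it$chrom]]
      L <- length(ch)
      if (it$span > L) stop("cluster longer than chromosome")
      new_start <- sample.int(L - it$span + 1L, 1) - 1L
      pos <- new_start + it$offsets
      base <- if (it$strand == "+") "C" else "G"
      hit <- ch[pos + 1L] == base
      n_base <- n_base + sum(hit)
      n_match <- n_match + sum(match_at_positions(ch, pos, motif, it$strand) & hit)
    }
    per_set[r] <- if (n_base > 0) n_match / n_base else NA_real_
    tot_match <- tot_match + n_match
    tot_base <- tot_base + n_base
  }
  if (all(is.na(per_set))) stop("relocated clusters hit no ancestral-base positions")
  list(ratio = mean(per_set, na.rm = TRUE), n_motif = tot_match,
       n_base = tot_base, per_set = per_set)
}

#' Local-context background
#'
#' Motif frequency among C/G positions within the union of windows (10 kb by
#' default) centered on the midpoints of the coordinated clusters, clipped at
#' chromosome ends. Controls for local nucleotide composition around the
#' clusters.
#'
#' @param cs a classified `cluster_set`.
#' @param motif a [motif].
#' @param window window size in bp centered on each cluster midpoint.
#' @return list with `ratio`, `n_motif`, `n_base`.
#' @export
local_context_background <- function(cs, motif, window = 10000) {
  ms <- cs_source(cs)
  cl <- cs$clusters[cs$clusters$type %in% c("C", "G"), , drop = FALSE]
  if (!nrow(cl)) stop("no coordinated clusters")
  n_motif <- 0
  n_base <- 0
  half <- floor(window / 2)
  for (chrom in unique(cl$chrom)) {
    s <- ms$ancestral[[chrom]]
    ch <- seq_chars(s)
    L <- length(ch)
    cc <- cl[cl$chrom == chrom, , drop = FALSE]
    mid <- floor((cc$start0 + cc$end0) / 2)
    wins <- data.frame(start0 = pmax(0, mid - half), end0 = pmin(L, mid + half))
    inwin <- interval_mask(normalize_regions(wins), L)
    pos <- genome_motif_positions(s, motif)
    n_motif <- n_motif + sum(inwin[pos$plus + 1L]) + sum(inwin[pos$minus + 1L])
    n_base <- n_base + sum(inwin & ch %in% c("C", "G"))
  }
  if (n_base == 0) stop("local-context windows contain no C or G nucleotides")
  list(ratio = n_motif / n_base, n_motif = n_motif, n_base = n_base)
}

#' Enrichment ratio and exact test
#'
#' E = signal / background. The one-tailed exact test compares motif versus
#' non-motif counts among clustered mutations against the background's motif
#' versus non-motif base counts (2x2 Fisher test in the enrichment
#' direction; no continuity correction).
#'
#' @param signal list from [motif_signal()] (`ratio`, `n_match`, `n_total`).
#' @param background list from one of the background functions (`ratio`,
#'   `n_motif`, `n_base`).
#' @param alternative `"greater"` for the one-tailed enrichment test.
#' @return list with `E` (Inf when the background ratio is zero), `fisher_p`.
#' @export
enrichment <- function(signal, background, alternative = "greater") {
  E <- if (background$ratio == 0) Inf else signal$ratio / background$ratio
  tab <- matrix(round(c(signal$n_match, signal$n_total - signal$n_match,
                        background$n_motif, background$n_base - background$n_motif)),
                nrow = 2, byrow = TRUE)
  fisher_p <- if (any(tab < 0) || sum(tab) == 0) NA_real_ else
    stats::fisher.test(tab, alternative = alternative)$p.value
  list(E = E, fisher_p = fisher_p)
}

#' Motif enrichment over a panel with a chosen background
#'
#' Computes, for each motif, the clustered-mutation signal, the requested
#' background, the enrichment ratio E, the one-tailed exact test and the
#' Bonferroni-adjusted q-value across the panel.
#'
#' @param cs a classified `cluster_set` built from a `mutation_set`.
#' @param motifs named list of [motif] objects (the panel tested in one run).
#' @param background one of `"genomic"`, `"random_mutations"`,
#'   `"random_clusters"`, `"local_context"`.
#' @param n_sets replicates for the randomized backgrounds.
#' @param window window size for the local-context background.
#' @param seed optional seed for the randomized backgrounds.
#' @param p_adjust `"bonferroni"` (default) or any method of
#'   [stats::p.adjust()].
#' @return data frame with one row per motif: label, pattern, mutated_index,
#'   background_mode, n_motif_mutations, n_total_mutations, signal,
#'   background, E, fisher_p, q.
#' @export
motif_enrichment <- function(cs, motifs = a3g_motif_panel(),
                             background = c("genomic", "random_mutations",
                                            "random_clusters", "local_context"),
                             n_sets = 100, window = 10000, seed = NULL,
                             p_adjust = "bonferroni") {
  background <- match.arg(background)
  rows <- lapply(motifs, function(mf) {
    sig <- motif_signal(cs, mf)
    bg <- switch(background,
                 genomic = genomic_background(cs_source(cs), mf),
                 random_mutations = random_mutation_background(cs, mf,
                                                               n_sets = n_sets,
                                                               seed = seed),
                 random_clusters = random_cluster_background(cs, mf,
                                                             n_sets = n_sets,
                                                             seed = seed),
                 local_context = local_context_background(cs, mf, window = window))
    e <- enrichment(sig, bg)
    data.frame(label = mf$label, pattern = mf$pattern,
               mutated_index = mf$mutated_index, background_mode = background,
               n_motif_mutations = sig$n_match, n_total_mutations = sig$n_total,
               signal = sig$ratio, background = bg$ratio, E = e$E,
               fisher_p = e$fisher_p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$fisher_p, method = p_adjust)
  out
}

#' Scan all 48 mutated-cytosine trinucleotides
#'
#' Every trinucleotide with a C at one of its three positions is tested as a
#' motif with the mutated position at that C (16 patterns per register,
#' 48 tests), against the genomic background, with Bonferroni correction
#' across the 48 tests. Patterns containing a CG dinucleotide are flagged as
#' CpG-containing, since their enrichment is confounded by spontaneous CpG
#' deamination.
#'
#' @param cs a classified `cluster_set`.
#' @param p_adjust multiple-testing method across the 48 tests.
#' @return data frame as [motif_enrichment()], plus `cpg` flag.
#' @export
trinucleotide_scan <- function(cs, p_adjust = "bonferroni") {
  ms <- cs_source(cs)
  # genomic triplet counts and C/G totals in one pass per chromosome
  tri <- stats::setNames(rep(0, 64), names(
    Biostrings::trinucleotideFrequency(Biostrings::DNAString("AAA"))))
  n_cg <- 0
  for (s in ms$ancestral) {
    d <- Biostrings::DNAString(s)
    tri <- tri + Biostrings::trinucleotideFrequency(d)
    af <- Biostrings::alphabetFrequency(d)
    n_cg <- n_cg + af[["C"]] + af[["G"]]
  }
  # per-mutation genome windows at each register, tabulated once; a minus
  # strand (G-cluster) match of pattern P at register m is a plus-orientation
  # window equal to revcomp(P) at the mirrored register 2 - m
  muts <- cs$mutations
  ctype <- mutation_cluster_types(cs)
  in_cg <- !is.na(ctype) & ctype %in% c("C", "G")
  n_total <- sum(in_cg)
  win_tab <- list(C = vector("list", 3), G = vector("list", 3))
  for (ty in c("C", "G")) {
    for (m in 0:2) {
      wins <- character(0)
      for (chrom in unique(muts$chrom)) {
        ch <- seq_chars(ms$ancestral[[chrom]])
        L <- length(ch)
        pos <- muts$pos0[muts$chrom == chrom & in_cg & ctype == ty]
        if (!length(pos)) next
        s0 <- pos - m
        ok <- s0 >= 0 & s0 + 3 <= L
        w <- rep("OUT", length(pos))
        w[ok] <- paste0(ch[s0[ok] + 1L], ch[s0[ok] + 2L], ch[s0[ok] + 3L])
        wins <- c(wins, w)
      }
      win_tab[[ty]][[m + 1]] <- table(wins)
    }
  }
  lookup <- function(tab, key) if (key %in% names(tab)) unname(tab[[key]]) else 0L
  rows <- list()
  for (m in 0:2) {
    others <- expand.grid(b1 = DNA_BASES, b2 = DNA_BASES,
                          stringsAsFactors = FALSE)
    for (i in seq_len(nrow(others))) {
      chars <- character(3)
      chars[m + 1] <- "C"
      chars[setdiff(1:3, m + 1)] <- c(others$b1[i], others$b2[i])
      pat <- paste(chars, collapse = "")
      rc <- revcomp(pat)
      n_match <- lookup(win_tab$C[[m + 1]], pat) +
        lookup(win_tab$G[[2 - m + 1]], rc)
      n_motif <- tri[[pat]] + tri[[rc]]
      sig <- list(ratio = if (n_total > 0) n_match / n_total else NA_real_,
                  n_match = n_match, n_total = n_total)
      bg <- list(ratio = n_motif / n_cg, n_motif = n_motif, n_base = n_cg)
      e <- enrichment(sig, bg)
      rows[[paste0(pat, ":", m)]] <- data.frame(
        label = paste0(pat, ":", m), pattern = pat, mutated_index = m,
        background_mode = "genomic", n_motif_mutations = n_match,
        n_total_mutations = n_total, signal = sig$ratio,
        background = bg$ratio, E = e$E, fisher_p = e$fisher_p)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  stopifnot(nrow(out) == 48)
  out$q <- stats::p.adjust(out$fisher_p, method = p_adjust)
  out$cpg <- grepl("CG", out$pattern, fixed = TRUE)
  out
}

#' CpG deamination controls for motif enrichment
#'
#' Three complementary controls that separate deaminase signal from
#' spontaneous CpG deamination: (a) enrichment recomputed on a CpG-filtered
#' mutation set against a CpG-masked genomic background; (b) enrichment with
#' motif matches at CCCG contexts (mutated C followed by G) excluded from
#' both numerator and genomic motif count; (c) an additivity decomposition of
#' per-site mutation rates over the strata CCC-only, CpG-only, CCC-and-CpG
#' and neither, counted over genomic C positions (plus strand) and G
#' positions (minus strand).
#'
#' @param cs a classified `cluster_set`.
#' @param motif the motif under control, A3G CCC by default.
#' @return list with `cpg_masked` and `cccg_excluded` (one-row enrichment
#'   data frames) and `additivity` (stratum table with site and mutation
#'   counts and per-site rates).
#' @export
cpg_controls <- function(cs, motif = motif_ccc()) {
  ms <- cs_source(cs)
  sig_a <- motif_signal(cs, motif, cpg_filter = TRUE)
  bg_a <- genomic_background(ms, motif, cpg_mask = TRUE)
  e_a <- enrichment(sig_a, bg_a)
  cpg_masked <- data.frame(label = motif$label, mode = "cpg_masked",
                           signal = sig_a$ratio, background = bg_a$ratio,
                           E = e_a$E, fisher_p = e_a$fisher_p,
                           n_motif_mutations = sig_a$n_match,
                           n_total_mutations = sig_a$n_total)
  sig_b <- motif_signal(cs, motif, exclude_cccg = TRUE)
  bg_b <- genomic_background(ms, motif, exclude_cccg = TRUE)
  e_b <- enrichment(sig_b, bg_b)
  cccg_excluded <- data.frame(label = motif$label, mode = "cccg_excluded",
                              signal = sig_b$ratio, background = bg_b$ratio,
                              E = e_b$E, fisher_p = e_b$fisher_p,
                              n_motif_mutations = sig_b$n_match,
                              n_total_mutations = sig_b$n_total)
  list(cpg_masked = cpg_masked, cccg_excluded = cccg_excluded,
       additivity = cpg_additivity(ms, motif))
}

# Per-site mutation rates over motif/CpG strata of genomic C (plus) and G
# (minus) positions; mutations at overlapping contexts (e.g. CCCG) count in
# both marginal strata and in the intersection stratum.
cpg_additivity <- function(ms, motif) {
  site_motif <- 0; site_cpg <- 0; site_both <- 0; site_neither <- 0
  mut_motif <- 0; mut_cpg <- 0; mut_both <- 0; mut_neither <- 0
  muts <- ms$mutations
  for (chrom in names(ms$ancestral)) {
    ch <- seq_chars(ms$ancestral[[chrom]])
    L <- length(ch)
    cpg_c <- c(ch[-L] == "C" & ch[-1] == "G", FALSE)
    cpg_g <- c(FALSE, ch[-L] == "C" & ch[-1] == "G")
    for (strand in c("+", "-")) {
      base <- if (strand == "+") "C" else "G"
      pos <- which(ch == base) - 1L
      in_motif <- match_at_positions(ch, pos, motif, strand)
      in_cpg <- if (strand == "+") cpg_c[pos + 1L] else cpg_g[pos + 1L]
      site_motif <- site_motif + sum(in_motif)
      site_cpg <- site_cpg + sum(in_cpg)
      site_both <- site_both + sum(in_motif & in_cpg)
      site_neither <- site_neither + sum(!in_motif & !in_cpg)
      mm <- muts[muts$chrom == chrom & muts$anc == base, , drop = FALSE]
      if (nrow(mm)) {
        i <- match(mm$pos0, pos)
        hit_motif <- !is.na(i) & in_motif[pmax(i, 1L)]
        hit_cpg <- !is.na(i) & in_cpg[pmax(i, 1L)]
        mut_motif <- mut_motif + sum(hit_motif)
        mut_cpg <- mut_cpg + sum(hit_cpg)
        mut_both <- mut_both + sum(hit_motif & hit_cpg)
        mut_neither <- mut_neither + sum(!is.na(i) & !hit_motif & !hit_cpg)
      }
    }
  }
  out <- data.frame(
    stratum = c("motif", "cpg", "motif_and_cpg", "neither"),
    sites = c(site_motif, site_cpg, site_both, site_neither),
    mutations = c(mut_motif, mut_cpg, mut_both, mut_neither))
  out$rate <- ifelse(out$sites > 0, out$mutations / out$sites, NA_real_)
  out
}

#' Enrichment as a function of cluster confidence
#'
#' Recomputes the enrichment E of a motif on the clusters surviving each
#' P-value threshold and correlates E with -log10(threshold). A positive
#' correlation indicates that higher-confidence clusters are purer in the
#' motif signal.
#'
#' @param cs a classified `cluster_set`.
#' @param thresholds at least three P-value thresholds.
#' @param motif a [motif].
#' @return list with `table` (threshold, E, n_total, n_match), `r` (Pearson
#'   correlation of E with -log10 threshold; NA with `constant = TRUE` when
#'   E does not vary), and `constant`.
#' @export
enrichment_vs_confidence <- function(cs, thresholds, motif = motif_ccc()) {
  if (length(thresholds) < 3) stop("at least 3 thresholds required")
  ms <- cs_source(cs)
  bg <- genomic_background(ms, motif)
  rows <- lapply(thresholds, function(t) {
    sub <- filter_by_pvalue(cs, t)
    res <- tryCatch(motif_signal(sub, motif), error = function(e) NULL)
    if (is.null(res)) {
      data.frame(threshold = t, E = NA_real_, n_total = 0, n_match = 0)
    } else {
      data.frame(threshold = t, E = res$ratio / bg$ratio,
                 n_total = res$n_total, n_match = res$n_match)
    }
  })
  tab <- do.call(rbind, rows)
  ok <- is.finite(tab$E)
  if (sum(ok) < 3) {
    return(list(table = tab, r = NA_real_, constant = FALSE))
  }
  if (stats::sd(tab$E[ok]) == 0) {
    return(list(table = tab, r = NA_real_, constant = TRUE))
  }
  r <- stats::cor(tab$E[ok], -log10(tab$threshold[ok]))
  list(table = tab, r = r, constant = FALSE)
}

#' Enrichment restricted to a region subset (or to nonclustered mutations)
#'
#' Recomputes the motif signal using only mutations inside the supplied
#' regions (clusters contribute per-mutation), against the genomic
#' background. With `set = "nonclustered"`, the signal is instead computed
#' over mutations outside any cluster (ancestral C tested plus-strand,
#' ancestral G minus-strand), the contrast used to compare clustered and
#' dispersed mutations.
#'
#' @param cs a classified `cluster_set`.
#' @param motif a [motif].
#' @param regions optional region data frame (chrom, start0, end0).
#' @param set `"clustered"` (default) or `"nonclustered"`.
#' @return one-row data frame with counts, signal, background, E, fisher_p.
#' @export
subset_enrichment <- function(cs, motif = motif_ccc(), regions = NULL,
                              set = c("clustered", "nonclustered")) {
  set <- match.arg(set)
  ms <- cs_source(cs)
  muts <- cs$mutations
  if (set == "clustered") {
    ctype <- mutation_cluster_types(cs)
    in_set <- !is.na(ctype) & ctype %in% c("C", "G")
    strand <- ifelse(ctype == "C", "+", "-")
  } else {
    in_set <- is.na(muts$cluster) & muts$anc %in% c("C", "G")
    strand <- ifelse(muts$anc == "C", "+", "-")
  }
  if (!is.null(regions)) {
    inreg <- rep(FALSE, nrow(muts))
    for (chrom in unique(muts$chrom)) {
      i <- muts$chrom == chrom
      inreg[i] <- positions_in_regions(muts$pos0[i],
                                       regions[regions$chrom == chrom, , drop = FALSE])
    }
    in_set <- in_set & inreg
  }
  if (!any(in_set)) stop("undefined signal: no mutations in the requested subset")
  flags <- logical(nrow(muts))
  for (chrom in unique(muts$chrom)) {
    ch <- seq_chars(ms$ancestral[[chrom]])
    for (sd in c("+", "-")) {
      i <- which(muts$chrom == chrom & in_set & strand == sd)
      flags[i] <- match_at_positions(ch, muts$pos0[i], motif, sd)
    }
  }
  sig <- list(ratio = sum(flags & in_set) / sum(in_set),
              n_match = sum(flags & in_set), n_total = sum(in_set))
  bg <- genomic_background(ms, motif)
  e <- enrichment(sig, bg)
  data.frame(label = motif$label, set = set,
             n_motif_mutations = sig$n_match, n_total_mutations = sig$n_total,
             signal = sig$ratio, background = bg$ratio, E = e$E,
             fisher_p = e$fisher_p)
}
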