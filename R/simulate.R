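# Synthetic data generator: ancestral genome, four-taxon alignment with
# per-branch background substitutions, planted A3G cluster events, lineage
# allele tracks and annotation intervals with a ground-truth table.

#' Generate the ancestral genome and annotation intervals
#'
#' Bases are drawn independently at the configured GC fraction and the CG
#' dinucleotide frequency is then adjusted towards
#' `cpg_enrichment * (gc/2)^2` per dinucleotide, either by planting extra CG
#' pairs (enrichment > 1) or by disrupting a fraction of the CG occurrences
#' (enrichment < 1). The base composition used for the independent draw is
#' pre-compensated so that the final GC fraction still matches
#' `gc_fraction`. Annotation intervals are placed uniformly without
#' within-track overlap; scored tracks get lognormal levels.
#'
#' @param config a [simulation_config()].
#' @return list with `sequence` (character scalar) and `annotations`
#'   (named list of 0-based half-open interval data frames).
#' @export
generate_ancestral_genome <- function(config) {
  config <- validate_simulation_config(config)
  set.seed(config$seed)
  list(sequence = gen_genome_sequence(config),
       annotations = gen_annotations(config))
}

gen_genome_sequence <- function(config) {
  paste(gen_genome_chars(config), collapse = "")
}

gen_genome_chars <- function(config) {
  L <- config$genome_length
  gc <- config$gc_fraction
  m <- config$cpg_enrichment
  if (gc == 0) {
    return(sample(c("A", "T"), L, replace = TRUE))
  }
  if (gc == 1) {
    # all-GC degenerate composition: CpG adjustment not meaningful
    return(sample(c("C", "G"), L, replace = TRUE))
  }
  # pre-compensate base GC for the CG planting / disruption step
  gc0 <- gc
  if (m > 1) {
    # joint fixed point: planted-pair rate kf and compensated base GC gc0,
    # with each planted CG overwriting ~3 dinucleotides of iid sequence
    target_cg <- m * (gc / 2)^2
    kf <- 0
    for (i in 1:20) {
      q <- (gc0 / 2)^2
      kf <- max(0, target_cg - q * (1 - 3 * kf))
      gc0 <- (gc - 2 * kf) / (1 - 2 * kf)
      if (gc0 <= 0.01) {
        stop("configuration error: 'cpg_enrichment' too large for gc_fraction")
      }
    }
    # inflate for the adjacent-start collisions dropped below
    k <- round(kf * (L - 1) / (1 - 2 * kf))
  } else if (m < 1) {
    # the GC compensation raises the iid CG rate, so the destruction
    # fraction is solved jointly with it
    target_cg <- m * (gc / 2)^2
    frac_destroy <- 0
    for (i in 1:20) {
      q <- (gc0 / 2)^2
      rf <- max(0, q - target_cg)
      gc0 <- min(0.99, gc + rf)
      frac_destroy <- if (q > 0) rf / q else 0
    }
  }
  p <- c(A = (1 - gc0) / 2, C = gc0 / 2, G = gc0 / 2, T = (1 - gc0) / 2)
  ch <- sample(DNA_BASES, L, replace = TRUE, prob = p)
  if (m > 1 && k > 0) {
    starts <- sort(sample.int(L - 1L, min(k, (L - 1L) %/% 2)))
    starts <- starts[c(TRUE, diff(starts) > 1)]
    ch[starts] <- "C"
    ch[starts + 1L] <- "G"
  } else if (m < 1) {
    cg <- which(ch[-L] == "C" & ch[-1] == "G")
    drop <- cg[stats::runif(length(cg)) < frac_destroy]
    if (length(drop)) {
      ch[drop] <- sample(c("T", "A"), length(drop), replace = TRUE, prob = c(0.6, 0.4))
    }
  }
  ch
}

gen_annotations <- function(config) {
  L <- config$genome_length
  out <- list()
  for (a in config$annotation_spec) {
    n <- a$n
    len <- a$length
    # one interval per equal genome slot: uniform-ish and never overlapping
    slot <- L %/% n
    if (len > slot) {
      stop(sprintf("configuration error: cannot place %d non-overlapping intervals of %d bp for track '%s'",
                   n, len, a$label))
    }
    starts <- as.integer((seq_len(n) - 1L) * slot) +
      vapply(seq_len(n), function(i) sample.int(slot - len + 1L, 1) - 1L, integer(1))
    len <- as.integer(len)
    df <- data.frame(chrom = config$chrom, start0 = starts, end0 = starts + len)
    if (isTRUE(a$scored)) df$level <- stats::rlnorm(n, meanlog = 1, sdlog = 1)
    out[[a$label]] <- df
  }
  out
}

#' Simulate independent background substitutions on each branch
#'
#' Every site mutates independently with the branch's per-bp probability;
#' cytosines followed by G and guanines preceded by C (CpG context) mutate at
#' `cpg_hypermutation_multiplier` times the base rate, biased towards the
#' deamination products C>T and G>A. Each branch's substitutions are drawn
#' from the supplied parent sequence, so a branch never mutates a site twice.
#'
#' @param sequence parent DNA sequence (character scalar).
#' @param branch_rates named vector of per-bp substitution probabilities, each
#'   in [0, 0.1].
#' @param cpg_hypermutation_multiplier CpG rate multiplier.
#' @param seed optional integer seed.
#' @return named list (one entry per branch) of data frames with columns
#'   `pos0`, `anc`, `der`, `cpg`.
#' @export
simulate_branch_mutations <- function(sequence, branch_rates,
                                      cpg_hypermutation_multiplier = 1,
                                      seed = NULL) {
  if (any(branch_rates < 0) || any(branch_rates > 0.1)) {
    stop("branch rates must lie in [0, 0.1] (low-homoplasy assumption)")
  }
  if (!is.null(seed)) set.seed(seed)
  ch <- seq_chars(sequence)
  lapply(branch_rates, function(r) {
    draw_branch_mutations(ch, r, cpg_hypermutation_multiplier)
  })
}

# Core per-branch draw on a character vector.
draw_branch_mutations <- function(ch, rate, cpg_mult) {
  L <- length(ch)
  if (rate == 0) {
    return(data.frame(pos0 = integer(0), anc = character(0),
                      der = character(0), cpg = logical(0)))
  }
  cpg_c <- c(ch[-L] == "C" & ch[-1] == "G", FALSE)
  cpg_g <- c(FALSE, ch[-L] == "C" & ch[-1] == "G")
  is_cpg <- (cpg_c & ch == "C") | (cpg_g & ch == "G")
  p <- rep(rate, L)
  p[is_cpg] <- pmin(0.95, rate * cpg_mult)
  hit <- which(stats::runif(L) < p)
  if (!length(hit)) {
    return(data.frame(pos0 = integer(0), anc = character(0),
                      der = character(0), cpg = logical(0)))
  }
  anc <- ch[hit]
  n <- length(hit)
  cpg_hit <- is_cpg[hit]
  # alternatives per ancestral base, ordered so column 1 is the transition
  alt <- rbind(A = c("G", "C", "T"), C = c("T", "A", "G"),
               G = c("A", "C", "T"), T = c("C", "A", "G"))
  # CpG deamination bias: the transition (C>T / G>A) dominates at CpG sites
  col <- ifelse(cpg_hit,
                sample.int(3L, n, replace = TRUE, prob = c(0.8, 0.1, 0.1)),
                sample.int(3L, n, replace = TRUE))
  der <- alt[cbind(match(anc, DNA_BASES), col)]
  data.frame(pos0 = hit - 1L, anc = anc, der = der, cpg = cpg_hit)
}

apply_mutations <- function(ch, muts) {
  if (nrow(muts)) ch[muts$pos0 + 1L] <- muts$der
  ch
}

#' Plant multi-mutation A3G cluster events on the target branch
#'
#' Events model single-generation deaminase processivity: each event draws a
#' size from the configured distribution, picks a strand (reverse with
#' probability `reverse_strand_prob`), and places same-strand cytosine
#' (plus strand) or guanine (minus strand) mutations at the mutated position
#' of CCC contexts (with probability `motif_fidelity` per mutation) or at
#' CC-but-not-CCC contexts, with consecutive spacing in
#' (`min_event_spacing` - 1, `a3g_span`]. Derived alleles are C>T with
#' probability `a3g_c_to_t_fraction`, otherwise C>G or C>A (complemented on
#' the minus strand).
#'
#' @param sequence the target-branch ancestral sequence (character scalar).
#' @param config a [simulation_config()].
#' @param seed optional integer seed (defaults to `config$seed`).
#' @param avoid_pos0 0-based positions that events must not touch (e.g.
#'   background-mutated sites).
#' @param n_events optional event count override; defaults to a Poisson draw
#'   at `a3g_event_rate * genome_length`.
#' @param anchor_weights optional data frame of scored intervals
#'   (start0/end0/level); when present, event anchors are sampled inside these
#'   intervals with probability proportional to level.
#' @return data frame of planted mutations with columns `event_id`, `pos0`,
#'   `anc`, `der`, `strand`, `motif` (CCC or CC at the planted register).
#' @export
plant_a3g_events <- function(sequence, config, seed = NULL,
                             avoid_pos0 = integer(0), n_events = NULL,
                             anchor_weights = NULL) {
  config <- validate_simulation_config(config)
  if (!is.null(seed)) set.seed(seed)
  ch <- if (length(sequence) > 1) sequence else seq_chars(sequence)
  L <- length(ch)
  if (is.null(n_events)) {
    n_events <- stats::rpois(1, config$a3g_event_rate * L)
  }
  empty <- data.frame(event_id = integer(0), pos0 = integer(0),
                      anc = character(0), der = character(0),
                      strand = character(0), motif = character(0))
  if (n_events == 0) return(empty)

  pools <- motif_position_pools(ch)
  if (length(pools$plus$ccc) + length(pools$plus$cc) < n_events) {
    stop(sprintf("insufficient motif density: %d eligible CC/CCC positions for %d requested events",
                 length(pools$plus$ccc) + length(pools$plus$cc), n_events))
  }
  used <- logical(L)
  if (length(avoid_pos0)) used[avoid_pos0 + 1L] <- TRUE

  weight_of <- make_anchor_weighter(anchor_weights, L)
  sizes <- as.integer(names(config$a3g_event_size))
  rows <- vector("list", n_events)
  placed <- 0L
  for (ev in seq_len(n_events)) {
    size <- sample(sizes, 1, prob = config$a3g_event_size)
    res <- place_one_event(pools, used, size, config, weight_of)
    if (is.null(res)) {
      stop(sprintf("insufficient motif density: placed %d of %d requested events before failing",
                   placed, n_events))
    }
    used[res$pos0 + 1L] <- TRUE
    placed <- placed + 1L
    strand <- res$strand
    n <- length(res$pos0)
    if (strand == "+") {
      der <- ifelse(stats::runif(n) < config$a3g_c_to_t_fraction, "T",
                    sample(c("G", "A"), n, replace = TRUE))
      anc <- rep("C", n)
    } else {
      der <- ifelse(stats::runif(n) < config$a3g_c_to_t_fraction, "A",
                    sample(c("C", "T"), n, replace = TRUE))
      anc <- rep("G", n)
    }
    rows[[ev]] <- data.frame(event_id = ev, pos0 = res$pos0, anc = anc,
                             der = der, strand = strand, motif = res$motif)
  }
  out <- do.call(rbind, rows)
  out[order(out$pos0), , drop = FALSE]
}

# Eligible planting positions (0-based), by strand and motif class.
# Plus strand: C at the 3' position of CCC / of CC-not-CCC.
# Minus strand: G at the 5' position of GGG / of GG-not-GGG (the reverse
# complement register of the plus-strand motifs).
motif_position_pools <- function(ch) {
  L <- length(ch)
  isC <- ch == "C"
  isG <- ch == "G"
  c1 <- c(FALSE, isC[-L])          # C at i-1
  c2 <- c(FALSE, FALSE, isC[-c(L - 1L, L)])  # C at i-2
  ccc <- which(isC & c1 & c2)
  cc <- which(isC & c1 & !c2)
  g1 <- c(isG[-1], FALSE)          # G at i+1
  g2 <- c(isG[-c(1L, 2L)], FALSE, FALSE)  # G at i+2
  ggg <- which(isG & g1 & g2)
  gg <- which(isG & g1 & !g2)
  list(plus = list(ccc = ccc - 1L, cc = cc - 1L),
       minus = list(ccc = ggg - 1L, cc = gg - 1L))
}

make_anchor_weighter <- function(anchor_weights, L) {
  if (is.null(anchor_weights)) return(NULL)
  check_intervals(anchor_weights)
  if (!"level" %in% names(anchor_weights)) {
    stop("anchor weighting requires a 'level' column")
  }
  w <- numeric(L)
  for (i in seq_len(nrow(anchor_weights))) {
    s <- anchor_weights$start0[i] + 1L
    e <- min(L, anchor_weights$end0[i])
    w[s:e] <- anchor_weights$level[i]
  }
  function(pos0) w[pos0 + 1L]
}

place_one_event <- function(pools, used, size, config, weight_of,
                            max_tries = 2000L) {
  lo <- config$min_event_spacing
  hi <- config$a3g_span
  fid <- config$motif_fidelity
  # at the extremes of motif_fidelity the other motif class is forbidden;
  # otherwise the per-mutation class draw may fall back to the other class
  # when its window holds no eligible position
  draw_classes <- function() {
    if (fid >= 1) return("ccc")
    if (fid <= 0) return("cc")
    if (stats::runif(1) < fid) c("ccc", "cc") else c("cc", "ccc")
  }
  for (try in seq_len(max_tries)) {
    strand <- if (stats::runif(1) < config$reverse_strand_prob) "-" else "+"
    pool <- pools[[if (strand == "+") "plus" else "minus"]]
    cls <- draw_classes()[1]
    cand <- pool[[cls]]
    cand <- cand[!used[cand + 1L]]
    if (!length(cand)) next
    anchor <- if (is.null(weight_of)) {
      cand[sample.int(length(cand), 1)]
    } else {
      w <- weight_of(cand)
      if (all(w == 0)) next
      cand[sample.int(length(cand), 1, prob = w)]
    }
    pos <- anchor
    motifs <- toupper(cls)
    ok <- TRUE
    prev <- anchor
    if (size > 1) {
      for (j in 2:size) {
        nxt <- next_event_position(pool, draw_classes(), prev, lo, hi, used, pos)
        if (is.null(nxt)) { ok <- FALSE; break }
        pos <- c(pos, nxt$pos)
        motifs <- c(motifs, nxt$motif)
        prev <- nxt$pos
      }
    }
    if (ok) return(list(pos0 = pos, strand = strand, motif = motifs))
  }
  NULL
}

next_event_position <- function(pool, classes, prev, lo, hi, used, taken) {
  for (c2 in classes) {
    v <- pool[[c2]]  # sorted ascending
    i1 <- findInterval(prev + lo - 1L, v) + 1L
    i2 <- findInterval(prev + hi, v)
    if (i2 < i1) next
    v <- v[i1:i2]
    v <- v[!used[v + 1L] & !(v %in% taken)]
    if (length(v)) {
      return(list(pos = v[sample.int(length(v), 1)], motif = toupper(c2)))
    }
  }
  NULL
}

#' Simulate the complete synthetic dataset
#'
#' Runs the full generator: ancestral genome and annotations, background
#' substitutions along every branch of the ((target,sister),outgroup1,
#' outgroup2) tree (the `internal` branch leads from the root to the
#' target-sister ancestor), planted A3G events on the target branch, the
#' lineage partition of target-branch mutations into three descendant
#' lineages, and the ground-truth table.
#'
#' @param config a [simulation_config()].
#' @return object of class `synthetic_dataset`: a list with `config`,
#'   `alignment` (a [species_alignment]), `truth` (one row per target-branch
#'   mutation: chrom, pos0, lineage, anc, der, event_id, event_class, strand,
#'   motif), `tracks` (long-format lineage allele table), `annotations`,
#'   `ancestor` (root sequence) and `target_ancestor` (target-sister ancestor
#'   carrying the internal-branch changes).
#' @export
simulate_dataset <- function(config) {
  config <- validate_simulation_config(config)
  set.seed(config$seed)
  L <- config$genome_length
  root <- gen_genome_chars(config)
  annotations <- gen_annotations(config)

  mult <- config$cpg_hypermutation_multiplier
  internal <- draw_branch_mutations(root, config$branch_rates[["internal"]], mult)
  og1 <- draw_branch_mutations(root, config$branch_rates[["outgroup1"]], mult)
  og2 <- draw_branch_mutations(root, config$branch_rates[["outgroup2"]], mult)
  h <- apply_mutations(root, internal)           # target-sister ancestor
  sister_m <- draw_branch_mutations(h, config$branch_rates[["sister"]], mult)
  target_m <- draw_branch_mutations(h, config$branch_rates[["target"]], mult)

  anchor_weights <- NULL
  if (!is.null(config$a3g_weight_by)) {
    anchor_weights <- annotations[[config$a3g_weight_by]]
  }
  events <- plant_a3g_events(h, config, avoid_pos0 = target_m$pos0,
                             anchor_weights = anchor_weights)

  target <- apply_mutations(apply_mutations(h, target_m), events)
  sister <- apply_mutations(h, sister_m)
  out1 <- apply_mutations(root, og1)
  out2 <- apply_mutations(root, og2)

  truth <- rbind(
    if (nrow(target_m)) data.frame(
      chrom = config$chrom, pos0 = target_m$pos0, anc = target_m$anc,
      der = target_m$der,
      event_id = paste0("bg", seq_len(nrow(target_m))),
      event_class = ifelse(target_m$cpg, "cpg", "background"),
      strand = "+", motif = NA_character_) else NULL,
    if (nrow(events)) data.frame(
      chrom = config$chrom, pos0 = events$pos0, anc = events$anc,
      der = events$der, event_id = paste0("a3g", events$event_id),
      event_class = "a3g", strand = events$strand, motif = events$motif) else NULL
  )
  if (is.null(truth)) {
    truth <- data.frame(chrom = character(0), pos0 = integer(0),
                        anc = character(0), der = character(0),
                        event_id = character(0), event_class = character(0),
                        strand = character(0), motif = character(0))
  }
  truth <- truth[order(truth$pos0), , drop = FALSE]
  rownames(truth) <- NULL
  truth$lineage <- assign_lineages(truth, config)

  tracks <- build_allele_tracks(truth, config)

  aln <- species_alignment(
    chrom = config$chrom,
    seqs = c(target = paste(target, collapse = ""),
             sister = paste(sister, collapse = ""),
             outgroup1 = paste(out1, collapse = ""),
             outgroup2 = paste(out2, collapse = "")))

  structure(list(config = config, alignment = aln, truth = truth,
                 tracks = tracks, annotations = annotations,
                 ancestor = paste(root, collapse = ""),
                 target_ancestor = paste(h, collapse = "")),
            class = "synthetic_dataset")
}

# Whole planted events share a lineage; background mutations are assigned
# independently.
assign_lineages <- function(truth, config) {
  lp <- config$lineage_proportions
  labs <- names(lp)
  lin <- character(nrow(truth))
  if (!nrow(truth)) return(lin)
  ids <- unique(truth$event_id)
  ev_lin <- stats::setNames(sample(labs, length(ids), replace = TRUE, prob = lp), ids)
  ev_lin[truth$event_id]
}

build_allele_tracks <- function(truth, config) {
  if (!nrow(truth)) {
    return(data.frame(chrom = character(0), pos0 = integer(0),
                      lineage = character(0), allele = character(0)))
  }
  do.call(rbind, lapply(config$lineage_labels, function(lab) {
    carries <- truth$lineage %in% c("common", lab)
    data.frame(chrom = truth$chrom, pos0 = truth$pos0, lineage = lab,
               allele = ifelse(carries, truth$der, truth$anc))
  }))
}

#' Construct a species alignment object
#'
#' A gap-free aligned set of equal-length sequences over one chromosome,
#' with the target genome first.
#'
#' @param chrom chromosome name.
#' @param seqs named character vector of aligned sequences
#'   (`target`, `sister`, `outgroup1`, `outgroup2`).
#' @return object of class `species_alignment`.
#' @export
species_alignment <- function(chrom, seqs) {
  stopifnot(all(c("target", "sister", "outgroup1", "outgroup2") %in% names(seqs)))
  if (length(unique(nchar(seqs))) != 1) {
    stop("aligned sequences must have equal length")
  }
  structure(list(chrom = chrom, seqs = seqs, length = nchar(seqs[[1]])),
            class = "species_alignment")
}

#' @export
print.species_alignment <- function(x, ...) {
  cat(sprintf("species_alignment: %s, %d bp, species: %s\n",
              x$chrom, x$length, paste(names(x$seqs), collapse = ", ")))
  invisible(x)
}

#' Reverse complement a species alignment
#'
#' Mirrors coordinates: position p maps to length - 1 - p. Used to check
#' strand symmetry of the calling and enrichment pipeline.
#'
#' @param aln a [species_alignment].
#' @return the reverse-complemented alignment.
#' @export
revcomp_alignment <- function(aln) {
  species_alignment(aln$chrom, vapply(aln$seqs, revcomp, character(1)))
}
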