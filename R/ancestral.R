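# Parsimony mutation calling from a four-taxon alignment: the sister allele,
# confirmed by at least one outgroup, is taken as the ancestral state of the
# target-sister ancestor; target-lineage substitutions are called where the
# target allele differs from it.

#' Extract per-position alignment columns
#'
#' Intended for small alignments and tests; the production path is
#' [call_mutations()], which operates on whole sequences.
#'
#' @param aln a [species_alignment].
#' @return data frame with columns chrom, pos0, target, sister, out1, out2.
#' @export
alignment_columns <- function(aln) {
  data.frame(chrom = aln$chrom,
             pos0 = 0:(aln$length - 1L),
             target = seq_chars(toupper(aln$seqs[["target"]])),
             sister = seq_chars(toupper(aln$seqs[["sister"]])),
             out1 = seq_chars(toupper(aln$seqs[["outgroup1"]])),
             out2 = seq_chars(toupper(aln$seqs[["outgroup2"]])))
}

#' Infer the ancestral state of alignment columns
#'
#' Returns the sister allele where it is a plain base and matches at least
#' one non-missing outgroup allele, and `NA` otherwise. Any non-ACGT symbol
#' (gap, N, ambiguity code) counts as missing.
#'
#' @param columns data frame as from [alignment_columns()].
#' @return character vector of ancestral bases, `NA` where not inferable.
#' @export
infer_ancestral_state <- function(columns) {
  s <- toupper(columns$sister)
  o1 <- toupper(columns$out1)
  o2 <- toupper(columns$out2)
  s_ok <- s %in% DNA_BASES
  conf <- (s_ok & o1 %in% DNA_BASES & s == o1) |
          (s_ok & o2 %in% DNA_BASES & s == o2)
  ifelse(conf, s, NA_character_)
}

#' Filter alignment columns by data completeness and exclusion masks
#'
#' Removes columns where the target or sister allele is missing, where both
#' outgroups are missing, or that overlap any exclusion mask. The count of
#' surviving columns is the callable length used downstream as the
#' denominator of the genome-wide mutation probability.
#'
#' @param columns data frame as from [alignment_columns()].
#' @param masks a region data frame, or named list of them, in 0-based
#'   half-open coordinates on the target.
#' @return list with `columns` (survivors), `callable_length`, and
#'   `callable` (surviving positions as an interval data frame).
#' @export
apply_masks <- function(columns, masks = NULL) {
  t <- toupper(columns$target)
  s <- toupper(columns$sister)
  keep <- t %in% DNA_BASES & s %in% DNA_BASES &
    (toupper(columns$out1) %in% DNA_BASES | toupper(columns$out2) %in% DNA_BASES)
  if (!is.null(masks)) {
    if (is.data.frame(masks)) masks <- list(masks)
    for (mk in masks) {
      check_intervals(mk)
      keep <- keep & !positions_in_regions(columns$pos0, mk)
    }
  }
  cols <- columns[keep, , drop = FALSE]
  list(columns = cols,
       callable_length = nrow(cols),
       callable = positions_to_intervals(cols$pos0, columns$chrom[1]))
}

positions_to_intervals <- function(pos0, chrom) {
  if (!length(pos0)) {
    return(data.frame(chrom = character(0), start0 = integer(0), end0 = integer(0)))
  }
  pos0 <- sort(pos0)
  brk <- c(TRUE, diff(pos0) > 1)
  grp <- cumsum(brk)
  data.frame(chrom = chrom,
             start0 = tapply(pos0, grp, min),
             end0 = tapply(pos0, grp, max) + 1L,
             row.names = NULL)
}

#' Call target-lineage mutations from filtered columns
#'
#' One mutation per column whose inferred ancestral state differs from the
#' target allele. The trinucleotide context is read from the target sequence
#' with the ancestral allele substituted at every called position, so that
#' motif evaluation reflects the pre-mutation haplotype.
#'
#' @param columns filtered columns (the `columns` element of [apply_masks()]).
#' @param lineage lineage label recorded on the calls.
#' @return mutation data frame (chrom, pos0, anc, der, lineage, context).
#' @export
call_lineage_mutations <- function(columns, lineage = "target") {
  anc <- infer_ancestral_state(columns)
  t <- toupper(columns$target)
  called <- !is.na(anc) & anc != t
  if (!any(called)) {
    return(data.frame(chrom = character(0), pos0 = integer(0),
                      anc = character(0), der = character(0),
                      lineage = character(0), context = character(0)))
  }
  # ancestral haplotype restricted to the provided columns
  h <- t
  h[called] <- anc[called]
  idx_of <- stats::setNames(seq_along(columns$pos0), columns$pos0)
  ctx_at <- function(p) {
    i <- idx_of[as.character(p)]
    ifelse(is.na(i), "N", h[i])
  }
  pos <- columns$pos0[called]
  context <- paste0(ctx_at(pos - 1L), h[which(called)], ctx_at(pos + 1L))
  out <- data.frame(chrom = columns$chrom[called], pos0 = pos,
                    anc = anc[called], der = t[called],
                    lineage = lineage, context = context)
  out[order(out$pos0), , drop = FALSE]
}

#' Call lineage-specific mutations from a species alignment
#'
#' The production entry point: applies the missing-data and mask filters,
#' infers ancestral states by outgroup-confirmed parsimony, calls
#' target-lineage substitutions and assembles the ancestral haplotype used
#' for motif context evaluation. Equivalent to
#' [alignment_columns()] + [apply_masks()] + [call_lineage_mutations()], but
#' vectorized over whole chromosomes.
#'
#' @param aln a [species_alignment].
#' @param masks region data frame or named list of them (0-based half-open).
#' @param lineage lineage label for the called mutations.
#' @return object of class `mutation_set`: list with `mutations` (data frame
#'   chrom, pos0, anc, der, lineage, context), `ancestral` (named list of
#'   ancestral haplotype strings per chromosome), `callable` (interval data
#'   frame), `callable_length` and `genome_length`.
#' @export
call_mutations <- function(aln, masks = NULL, lineage = "target") {
  t <- seq_chars(toupper(aln$seqs[["target"]]))
  s <- seq_chars(toupper(aln$seqs[["sister"]]))
  o1 <- seq_chars(toupper(aln$seqs[["outgroup1"]]))
  o2 <- seq_chars(toupper(aln$seqs[["outgroup2"]]))
  L <- length(t)

  keep <- t %in% DNA_BASES & s %in% DNA_BASES &
    (o1 %in% DNA_BASES | o2 %in% DNA_BASES)
  if (!is.null(masks)) {
    if (is.data.frame(masks)) masks <- list(masks)
    for (mk in masks) keep <- keep & !interval_mask(mk, L)
  }
  conf <- keep & ((s == o1 & o1 %in% DNA_BASES) | (s == o2 & o2 %in% DNA_BASES))
  called <- conf & s != t

  h <- t
  h[called] <- s[called]

  idx <- which(called)
  ctx_left <- ifelse(idx > 1L, h[pmax(idx - 1L, 1L)], "N")
  ctx_right <- ifelse(idx < L, h[pmin(idx + 1L, L)], "N")
  mutations <- data.frame(
    chrom = aln$chrom,
    pos0 = idx - 1L,
    anc = s[idx],
    der = t[idx],
    lineage = lineage,
    context = paste0(ctx_left, h[idx], ctx_right))
  if (!nrow(mutations)) {
    mutations <- data.frame(chrom = character(0), pos0 = integer(0),
                            anc = character(0), der = character(0),
                            lineage = character(0), context = character(0))
  }

  structure(list(
    mutations = mutations,
    ancestral = stats::setNames(list(paste(h, collapse = "")), aln$chrom),
    callable = positions_to_intervals(which(keep) - 1L, aln$chrom),
    callable_length = sum(keep),
    genome_length = stats::setNames(L, aln$chrom)
  ), class = "mutation_set")
}

#' @export
print.mutation_set <- function(x, ...) {
  cat(sprintf("mutation_set: %d mutations on %s, callable length %d of %d bp\n",
              nrow(x$mutations), paste(names(x$genome_length), collapse = ","),
              x$callable_length, sum(x$genome_length)))
  invisible(x)
}

#' Construct a mutation set from a mutation table
#'
#' Wraps a precomputed mutation table (e.g. a truth table or an imported
#' TSV) together with the reference/ancestral sequence so that the cluster
#' and motif stages can run on it.
#'
#' @param mutations data frame with chrom, pos0, anc, der and optionally
#'   lineage; context is recomputed from `ancestral_seq` when absent.
#' @param ancestral_seq named list (by chromosome) of ancestral haplotype
#'   strings.
#' @param callable optional callable-interval data frame; defaults to the
#'   whole genome.
#' @return a `mutation_set`.
#' @export
mutation_set <- function(mutations, ancestral_seq, callable = NULL) {
  stopifnot(all(c("chrom", "pos0", "anc", "der") %in% names(mutations)))
  if (!"lineage" %in% names(mutations)) mutations$lineage <- "target"
  glen <- vapply(ancestral_seq, nchar, numeric(1))
  if (is.null(callable)) {
    callable <- data.frame(chrom = names(glen), start0 = 0L, end0 = unname(glen))
  }
  if (!"context" %in% names(mutations)) {
    mutations$context <- vapply(seq_len(nrow(mutations)), function(i) {
      ch <- seq_chars(ancestral_seq[[mutations$chrom[i]]])
      p <- mutations$pos0[i] + 1L
      paste0(if (p > 1) ch[p - 1] else "N", ch[p],
             if (p < length(ch)) ch[p + 1] else "N")
    }, character(1))
  }
  mutations <- mutations[order(mutations$chrom, mutations$pos0), , drop = FALSE]
  rownames(mutations) <- NULL
  structure(list(mutations = mutations, ancestral = ancestral_seq,
                 callable = callable,
                 callable_length = sum(callable$end0 - callable$start0),
                 genome_length = glen),
            class = "mutation_set")
}

#' Partition mutations among descendant lineages using allele tracks
#'
#' A mutation carried (derived) in every tracked lineage is labelled
#' `common`; carried in exactly one, that lineage's label; carried in a
#' strict subset, or with missing track data, `unassigned`.
#'
#' @param mutations mutation data frame (chrom, pos0, anc, der, ...).
#' @param tracks long-format allele table (chrom, pos0, lineage, allele).
#' @return the mutation data frame with its `lineage` column replaced by the
#'   partition label.
#' @export
partition_by_lineage <- function(mutations, tracks) {
  lineages <- unique(tracks$lineage)
  key <- function(chrom, pos0) paste(chrom, pos0)
  lab <- character(nrow(mutations))
  carried <- matrix(NA, nrow(mutations), length(lineages),
                    dimnames = list(NULL, lineages))
  for (ln in lineages) {
    tr <- tracks[tracks$lineage == ln, ]
    i <- match(key(mutations$chrom, mutations$pos0), key(tr$chrom, tr$pos0))
    allele <- tr$allele[i]
    bad <- !is.na(allele) & allele != mutations$anc & allele != mutations$der
    if (any(bad)) {
      stop("consistency error: track allele matches neither ancestral nor derived state")
    }
    carried[, ln] <- allele == mutations$der
  }
  n_car <- rowSums(carried, na.rm = TRUE)
  any_na <- rowSums(is.na(carried)) > 0
  lab[any_na] <- "unassigned"
  lab[!any_na & n_car == length(lineages)] <- "common"
  one <- !any_na & n_car == 1
  if (any(one)) {
    lab[one] <- lineages[apply(carried[one, , drop = FALSE], 1, which)]
  }
  lab[!any_na & n_car > 1 & n_car < length(lineages)] <- "unassigned"
  lab[!any_na & n_car == 0] <- "unassigned"
  mutations$lineage <- lab
  mutations
}
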