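# Block bootstrap: standard errors and percentile intervals for scalar
# statistics of position-indexed data, respecting local genomic correlation
# by resampling contiguous blocks with replacement.

#' Tile the genome into equal-sized blocks
#'
#' Contiguous non-overlapping blocks per chromosome; the last block of each
#' chromosome may be short.
#'
#' @param genome_extents named vector of chromosome lengths, or a data frame
#'   with chrom/start0/end0 extents.
#' @param block_size block size in bp (production default 90 kb).
#' @return object of class `block_scheme`: data frame of blocks (chrom,
#'   start0, end0, block) with attributes `block_size` and `n_blocks`.
#' @export
make_blocks <- function(genome_extents, block_size = 90000) {
  if (block_size <= 0) stop("block_size must be positive")
  if (!is.data.frame(genome_extents)) {
    genome_extents <- data.frame(chrom = names(genome_extents), start0 = 0,
                                 end0 = as.numeric(genome_extents))
  }
  check_intervals(genome_extents)
  if (!nrow(genome_extents)) stop("empty genome extents")
  rows <- lapply(seq_len(nrow(genome_extents)), function(i) {
    s <- genome_extents$start0[i]
    e <- genome_extents$end0[i]
    starts <- seq(s, e - 1, by = block_size)
    data.frame(chrom = genome_extents$chrom[i], start0 = starts,
               end0 = pmin(starts + block_size, e))
  })
  out <- do.call(rbind, rows)
  out$block <- seq_len(nrow(out))
  attr(out, "block_size") <- block_size
  attr(out, "n_blocks") <- nrow(out)
  class(out) <- c("block_scheme", "data.frame")
  out
}

#' Block-bootstrap standard error of a statistic
#'
#' Each replicate draws `n_blocks` blocks with replacement, pools the data
#' rows falling in the drawn blocks (rows are duplicated when a block is
#' drawn twice), and recomputes the statistic. Reported are the standard
#' deviation across replicates (the bootstrap SE) and the 2.5/97.5
#' percentiles.
#'
#' @param data data frame with `chrom` and `pos0` columns.
#' @param statistic function of a data-frame subset returning a scalar.
#' @param scheme a [make_blocks()] scheme.
#' @param n_boot number of replicates (10,000 for production; tests use
#'   a few hundred).
#' @param seed optional seed.
#' @return list with `se`, `ci` (2.5%/97.5%), `replicates`, `n_boot`.
#' @export
block_bootstrap <- function(data, statistic, scheme, n_boot = 10000,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nb <- attr(scheme, "n_blocks")
  if (is.null(nb)) nb <- nrow(scheme)
  if (nb < 2) stop("need at least 2 blocks")
  # assign rows to blocks
  row_block <- integer(nrow(data))
  for (chrom in unique(data$chrom)) {
    bl <- scheme[scheme$chrom == chrom, , drop = FALSE]
    bl <- bl[order(bl$start0), , drop = FALSE]
    i <- which(data$chrom == chrom)
    j <- findInterval(data$pos0[i], bl$start0)
    ok <- j >= 1 & data$pos0[i] < bl$end0[pmax(j, 1)]
    row_block[i[ok]] <- bl$block[j[ok]]
  }
  by_block <- split(seq_len(nrow(data)), factor(row_block, levels = seq_len(nb)))
  reps <- numeric(n_boot)
  for (r in seq_len(n_boot)) {
    drawn <- sample.int(nb, nb, replace = TRUE)
    rows <- unlist(by_block[drawn], use.names = FALSE)
    reps[r] <- statistic(data[rows, , drop = FALSE])
  }
  bad <- !is.finite(reps)
  if (mean(bad) > 0.01) {
    stop(sprintf("statistic undefined on %.1f%% of bootstrap replicates", 100 * mean(bad)))
  }
  reps_ok <- reps[!bad]
  list(se = stats::sd(reps_ok),
       ci = stats::quantile(reps_ok, c(0.025, 0.975), names = TRUE),
       replicates = reps, n_boot = n_boot)
}

#' Block-bootstrap SE of a motif enrichment ratio
#'
#' Resamples the clustered C/G mutations by genomic block and recomputes
#' E = (motif fraction among pooled clustered mutations) / background, with
#' the background held fixed (cluster memberships are not re-derived: at the
#' default block size, clusters are five orders of magnitude shorter than a
#' block, so resampling blocks resamples whole clusters).
#'
#' @param cs a classified `cluster_set`.
#' @param motif a [motif].
#' @param scheme a [make_blocks()] scheme (defaults to 90-kb tiling of the
#'   source genome).
#' @param n_boot replicates.
#' @param seed optional seed.
#' @param background fixed background ratio; genomic background by default
#'   (CpG-masked when `cpg_filter` is set).
#' @param cpg_filter drop mutations whose mutated base lies in a CpG, and use
#'   the CpG-masked genomic background, as in the CpG control analysis.
#' @return list with `E`, `se`, `ci`.
#' @export
bootstrap_enrichment <- function(cs, motif, scheme = NULL, n_boot = 200,
                                 seed = NULL, background = NULL,
                                 cpg_filter = FALSE) {
  ms <- cs_source(cs)
  if (is.null(scheme)) scheme <- make_blocks(ms$genome_length)
  if (is.null(background)) {
    background <- genomic_background(ms, motif, cpg_mask = cpg_filter)
  }
  ctype <- mutation_cluster_types(cs)
  in_cg <- !is.na(ctype) & ctype %in% c("C", "G")
  flags <- motif_match_flags(cs, motif)
  if (cpg_filter) {
    strand <- ifelse(ctype == "C", "+", "-")
    cpg <- rep(FALSE, nrow(cs$mutations))
    for (chrom in unique(cs$mutations$chrom)) {
      i <- which(cs$mutations$chrom == chrom & in_cg)
      cpg[i] <- mutated_base_in_cpg(ms, chrom, cs$mutations$pos0[i], strand[i])
    }
    in_cg <- in_cg & !cpg
  }
  dat <- data.frame(chrom = cs$mutations$chrom[in_cg],
                    pos0 = cs$mutations$pos0[in_cg],
                    match = flags[in_cg])
  if (!nrow(dat)) stop("no clustered C/G mutations to resample")
  stat <- function(d) if (nrow(d) == 0) NA_real_ else mean(d$match) / background$ratio
  bb <- block_bootstrap(dat, stat, scheme, n_boot = n_boot, seed = seed)
  list(E = mean(dat$match) / background$ratio, se = bb$se, ci = bb$ci)
}

#' Block-bootstrap SE of a region fold-change
#'
#' Pools A3G and control mutations, resamples blocks, and recomputes the
#' in-region fold-change on each replicate.
#'
#' @param a3g_set,control_set mutation data frames.
#' @param regions region data frame.
#' @param scheme a [make_blocks()] scheme.
#' @param n_boot replicates.
#' @param seed optional seed.
#' @return list with `fold_change`, `se`, `ci`.
#' @export
bootstrap_fold_change <- function(a3g_set, control_set, regions, scheme,
                                  n_boot = 200, seed = NULL) {
  regions <- normalize_regions(regions)
  mark <- function(muts, set) {
    inreg <- rep(FALSE, nrow(muts))
    for (chrom in unique(muts$chrom)) {
      i <- muts$chrom == chrom
      inreg[i] <- positions_in_regions(
        muts$pos0[i], regions[regions$chrom == chrom, , drop = FALSE])
    }
    data.frame(chrom = muts$chrom, pos0 = muts$pos0, set = set, inreg = inreg)
  }
  dat <- rbind(mark(a3g_set, "a3g"), mark(control_set, "control"))
  stat <- function(d) {
    a <- d$set == "a3g"
    if (!any(a) || !any(!a) || !any(d$inreg[!a])) return(NA_real_)
    mean(d$inreg[a]) / mean(d$inreg[!a])
  }
  bb <- block_bootstrap(dat, stat, scheme, n_boot = n_boot, seed = seed)
  list(fold_change = stat(dat), se = bb$se, ci = bb$ci)
}
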