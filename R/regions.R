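# Functional-region analyses: fold-change of A3G-set versus control
# mutations across annotations, expression-decile correlation, and
# branch-versus-branch differential accumulation.

count_in_regions <- function(muts, regions) {
  n <- 0L
  for (chrom in unique(muts$chrom)) {
    i <- muts$chrom == chrom
    n <- n + sum(positions_in_regions(
      muts$pos0[i], regions[regions$chrom == chrom, , drop = FALSE]))
  }
  n
}

#' Fold-change of A3G mutations versus control mutations in a region set
#'
#' The ratio of the in-region fraction of the A3G-induced mutation set to the
#' in-region fraction of the control set (all other mutations). A mutation
#' falls in a region when its single-base position lies inside the half-open
#' interval; clusters contribute per mutation. Tested with a two-tailed
#' exact test on the 2x2 count table.
#'
#' @param a3g_set data frame of A3G-set mutations (chrom, pos0, ...).
#' @param control_set data frame of control mutations.
#' @param regions region data frame (chrom, start0, end0), overlaps allowed
#'   (they are merged before counting).
#' @param label region label recorded in the output.
#' @return one-row data frame: label, a3g_in, a3g_total, control_in,
#'   control_total, fold_change (Inf flagged when the control fraction is
#'   zero), p.
#' @export
region_fold_change <- function(a3g_set, control_set, regions, label = "region") {
  if (!nrow(a3g_set) || !nrow(control_set)) {
    stop("both mutation sets must be nonempty")
  }
  regions <- normalize_regions(regions)
  a_in <- count_in_regions(a3g_set, regions)
  c_in <- count_in_regions(control_set, regions)
  a_tot <- nrow(a3g_set)
  c_tot <- nrow(control_set)
  fc <- if (c_in == 0) Inf else (a_in / a_tot) / (c_in / c_tot)
  tab <- matrix(c(a_in, a_tot - a_in, c_in, c_tot - c_in), 2, byrow = TRUE)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  data.frame(label = label, a3g_in = a_in, a3g_total = a_tot,
             control_in = c_in, control_total = c_tot,
             fold_change = fc, p = p)
}

#' Fold-change across a panel of region sets, with multiple-testing control
#'
#' @param a3g_set,control_set mutation data frames.
#' @param region_panel named list of region data frames.
#' @param p_adjust `"bonferroni"` (default) or `"BH"`.
#' @return data frame with one row per region set, plus `q`.
#' @export
region_panel_fold_change <- function(a3g_set, control_set, region_panel,
                                     p_adjust = "bonferroni") {
  out <- do.call(rbind, lapply(names(region_panel), function(lab) {
    region_fold_change(a3g_set, control_set, region_panel[[lab]], label = lab)
  }))
  out$q <- stats::p.adjust(out$p, method = p_adjust)
  out
}

#' Correlation of A3G fold-change with expression level across deciles
#'
#' Transcribed bases are partitioned into ten deciles by interval expression
#' level (length-weighted: intervals are sorted by level and split so each
#' decile holds one tenth of the annotated bases). The fold-change of A3G
#' versus control mutations is computed per decile, and the Pearson
#' correlation of fold-change with the decile's mean expression level is
#' reported over the first nine deciles; the top decile is reported
#' separately, as the most highly transcribed regions are under distinct
#' selective constraint.
#'
#' @param a3g_set,control_set mutation data frames.
#' @param expression_regions region data frame with a numeric `level` column.
#' @return list with `deciles` (decile, mean_level, counts, fold_change),
#'   `r` (Pearson correlation over deciles 1-9), and `top_decile` (row 10).
#' @export
expression_decile_correlation <- function(a3g_set, control_set,
                                          expression_regions) {
  check_intervals(expression_regions)
  if (!"level" %in% names(expression_regions)) {
    stop("expression regions require a 'level' column")
  }
  if (length(unique(expression_regions$level)) < 10) {
    stop("cannot form deciles: fewer than 10 distinct expression levels")
  }
  rg <- expression_regions[order(expression_regions$level), , drop = FALSE]
  widths <- rg$end0 - rg$start0
  total <- sum(widths)
  target <- total / 10
  # split intervals across decile boundaries so deciles are equal in bases
  pieces <- list()
  cum <- 0
  for (i in seq_len(nrow(rg))) {
    s <- rg$start0[i]; e <- rg$end0[i]
    while (s < e) {
      dec <- min(10L, floor(cum / target) + 1L)
      room <- ceiling(dec * target - cum)
      take <- min(e - s, max(1, room))
      pieces[[length(pieces) + 1]] <- data.frame(
        chrom = rg$chrom[i], start0 = s, end0 = s + take,
        level = rg$level[i], decile = dec)
      s <- s + take
      cum <- cum + take
    }
  }
  pieces <- do.call(rbind, pieces)
  rows <- lapply(1:10, function(d) {
    pp <- pieces[pieces$decile == d, , drop = FALSE]
    a_in <- count_in_regions(a3g_set, pp)
    c_in <- count_in_regions(control_set, pp)
    fc <- if (c_in == 0) NA_real_ else
      (a_in / nrow(a3g_set)) / (c_in / nrow(control_set))
    data.frame(decile = d,
               bases = sum(pp$end0 - pp$start0),
               mean_level = sum(pp$level * (pp$end0 - pp$start0)) /
                 sum(pp$end0 - pp$start0),
               a3g_in = a_in, control_in = c_in, fold_change = fc)
  })
  dec <- do.call(rbind, rows)
  first9 <- dec[dec$decile <= 9 & is.finite(dec$fold_change), , drop = FALSE]
  r <- if (nrow(first9) >= 3 && stats::sd(first9$fold_change) > 0) {
    stats::cor(first9$fold_change, first9$mean_level)
  } else NA_real_
  list(deciles = dec, r = r, top_decile = dec[dec$decile == 10, , drop = FALSE])
}

#' Differential A3G accumulation between two branches across region families
#'
#' For each region family (e.g. one transcription factor's binding regions),
#' compares the fraction of branch-A A3G mutations falling in the family with
#' the branch-B fraction by a two-tailed exact test, and reports per-branch
#' fold-changes when control sets are supplied. Families with no mutations in
#' either branch are skipped with a message.
#'
#' @param region_families named list of region data frames.
#' @param mutations_branch_a,mutations_branch_b branch-labelled A3G mutation
#'   data frames.
#' @param control_a,control_b optional control sets for per-branch
#'   fold-changes.
#' @param p_adjust FDR method for `q` (default `"BH"`; nominal p always
#'   reported).
#' @return data frame with one row per retained family: in/total counts per
#'   branch, per-branch fold-change (NA without controls), direction, p, q.
#' @export
branch_comparison <- function(region_families, mutations_branch_a,
                              mutations_branch_b, control_a = NULL,
                              control_b = NULL, p_adjust = "BH") {
  rows <- list()
  for (fam in names(region_families)) {
    regions <- normalize_regions(region_families[[fam]])
    a_in <- count_in_regions(mutations_branch_a, regions)
    b_in <- count_in_regions(mutations_branch_b, regions)
    if (a_in == 0 && b_in == 0) {
      message(sprintf("branch_comparison: family '%s' has no mutations in either branch; skipped", fam))
      next
    }
    a_tot <- nrow(mutations_branch_a)
    b_tot <- nrow(mutations_branch_b)
    tab <- matrix(c(a_in, a_tot - a_in, b_in, b_tot - b_in), 2, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    fc_a <- if (!is.null(control_a)) {
      region_fold_change(mutations_branch_a, control_a, regions, fam)$fold_change
    } else NA_real_
    fc_b <- if (!is.null(control_b)) {
      region_fold_change(mutations_branch_b, control_b, regions, fam)$fold_change
    } else NA_real_
    rows[[fam]] <- data.frame(
      family = fam, a_in = a_in, a_total = a_tot, b_in = b_in, b_total = b_tot,
      fold_change_a = fc_a, fold_change_b = fc_b,
      direction = if (a_in / a_tot >= b_in / b_tot) "branch_a" else "branch_b",
      p = p)
  }
  if (!length(rows)) {
    return(data.frame(family = character(0), a_in = integer(0),
                      a_total = integer(0), b_in = integer(0),
                      b_total = integer(0), fold_change_a = numeric(0),
                      fold_change_b = numeric(0), direction = character(0),
                      p = numeric(0), q = numeric(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$q <- stats::p.adjust(out$p, method = p_adjust)
  out
}
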