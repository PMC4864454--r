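# Shared low-level helpers: IUPAC handling, reverse complements, interval
# logic on 0-based half-open coordinates.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), R = c("A", "G"), Y = c("C", "T"),
  S = c("C", "G"), K = c("G", "T"), M = c("A", "C"),
  N = c("A", "C", "G", "T")
)

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings (IUPAC-aware)
#'
#' @param x character vector of DNA/IUPAC strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- chartr("ACGTWRYSKMNacgtwryskmn", "TGCAWYRSMKNtgcawyrsmkn", x)
  vapply(comp, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

complement_base <- function(x) chartr("ACGT", "TGCA", x)

seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Logical mask (length L) covering a set of 0-based half-open intervals.
interval_mask <- function(regions, L) {
  m <- logical(L)
  if (is.null(regions) || nrow(regions) == 0) return(m)
  check_intervals(regions)
  for (i in seq_len(nrow(regions))) {
    s <- max(0L, regions$start0[i])
    e <- min(L, regions$end0[i])
    if (e > s) m[(s + 1L):e] <- TRUE
  }
  m
}

check_intervals <- function(regions) {
  stopifnot(is.data.frame(regions))
  if (!all(c("start0", "end0") %in% names(regions))) {
    stop("region table must have columns 'start0' and 'end0' (0-based half-open)")
  }
  if (any(regions$start0 > regions$end0)) {
    stop("malformed interval: start greater than end")
  }
  invisible(regions)
}

# Convert a 0-based half-open region data.frame to an IRanges object.
regions_to_iranges <- function(regions) {
  IRanges::IRanges(start = regions$start0 + 1L, end = regions$end0)
}

# Which 0-based positions fall inside the (single-chromosome) region set.
positions_in_regions <- function(pos0, regions) {
  if (is.null(regions) || nrow(regions) == 0) return(rep(FALSE, length(pos0)))
  q <- IRanges::IRanges(start = pos0 + 1L, width = 1L)
  IRanges::overlapsAny(q, regions_to_iranges(regions))
}

# Merge overlapping/adjacent intervals; optional length-weighted level merge.
normalize_regions <- function(regions) {
  check_intervals(regions)
  if (nrow(regions) == 0) return(regions)
  has_level <- "level" %in% names(regions)
  ir <- regions_to_iranges(regions)
  red <- IRanges::reduce(ir)
  out <- data.frame(start0 = IRanges::start(red) - 1L, end0 = IRanges::end(red))
  if ("chrom" %in% names(regions)) out$chrom <- regions$chrom[1]
  if (has_level) {
    hits <- IRanges::findOverlaps(ir, red)
    lev <- numeric(length(red))
    wts <- numeric(length(red))
    w <- IRanges::width(ir)
    for (i in seq_along(hits)) {
      j <- S4Vectors::subjectHits(hits)[i]
      k <- S4Vectors::queryHits(hits)[i]
      lev[j] <- lev[j] + regions$level[k] * w[k]
      wts[j] <- wts[j] + w[k]
    }
    out$level <- lev / wts
  }
  out[order(out$start0), , drop = FALSE]
}

assert_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("configuration error: '%s' must be a single proportion in [0, 1]", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
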