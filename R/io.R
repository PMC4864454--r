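# Readers and writers for the interchange formats: aligned multi-FASTA and
# single-block MAF for the four-species alignment, BED3/BED5 annotations
# (0-based half-open, via rtracklayer), and TSV tables for mutations, truth
# and lineage allele tracks.

#' Write an aligned multi-FASTA
#' @param aln a [species_alignment].
#' @param path output path.
#' @export
write_alignment_fasta <- function(aln, path) {
  x <- Biostrings::DNAStringSet(aln$seqs)
  names(x) <- paste0(names(aln$seqs), ".", aln$chrom)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read an aligned multi-FASTA written by [write_alignment_fasta()]
#' @param path FASTA path; records named `<species>.<chrom>`.
#' @return a [species_alignment].
#' @export
read_alignment_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\..*$", "", names(x))
  chrom <- sub("^[^.]*\\.", "", names(x)[1])
  seqs <- stats::setNames(as.character(x), nm)
  species_alignment(chrom = chrom, seqs = seqs)
}

#' Write a single-block MAF alignment
#'
#' One alignment block covering the whole chromosome, all sequences on the
#' plus strand. MAF uses 0-based starts, matching the package convention.
#'
#' @param aln a [species_alignment].
#' @param path output path.
#' @export
write_maf <- function(aln, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  writeLines("a score=0", con)
  L <- aln$length
  for (sp in names(aln$seqs)) {
    writeLines(sprintf("s %s.%s 0 %d + %d %s", sp, aln$chrom, L, L,
                       aln$seqs[[sp]]), con)
  }
  writeLines("", con)
  invisible(path)
}

#' Read a single-block MAF alignment
#' @param path MAF path as written by [write_maf()].
#' @return a [species_alignment].
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  s <- lines[startsWith(lines, "s ")]
  if (!length(s)) stop("no sequence lines in MAF")
  parts <- strsplit(trimws(s), "\\s+")
  nm <- vapply(parts, function(p) sub("\\..*$", "", p[2]), character(1))
  chrom <- sub("^[^.]*\\.", "", parts[[1]][2])
  seqs <- stats::setNames(vapply(parts, function(p) p[7], character(1)), nm)
  species_alignment(chrom = chrom, seqs = seqs)
}

#' Write regions as BED (0-based half-open)
#'
#' BED3 for plain interval sets; BED5 (name ".", score = level) when the
#' region table carries a `level` column.
#'
#' @param regions region data frame (chrom, start0, end0, optional level).
#' @param path output path ending in `.bed`.
#' @export
write_bed <- function(regions, path) {
  check_intervals(regions)
  gr <- GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start0 + 1L, end = regions$end0))
  if ("level" %in% names(regions)) {
    S4Vectors::mcols(gr)$name <- rep(".", length(gr))
    S4Vectors::mcols(gr)$score <- regions$level
  }
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into a 0-based half-open region table
#' @param path BED path.
#' @return data frame with chrom, start0, end0 and `level` when a score
#'   column is present.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  out <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                    start0 = GenomicRanges::start(gr) - 1L,
                    end0 = GenomicRanges::end(gr))
  sc <- S4Vectors::mcols(gr)$score
  if (!is.null(sc) && !all(is.na(sc))) out$level <- as.numeric(sc)
  out
}

#' Write a mutation table as TSV
#' @param mutations mutation data frame.
#' @param path output path.
#' @export
write_mutations_tsv <- function(mutations, path) {
  utils::write.table(mutations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a mutation (or truth, or track) TSV
#' @param path TSV path with header.
#' @return data frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    colClasses = NA)
}

#' Write all fixture files of a synthetic dataset
#'
#' Writes the aligned multi-FASTA and MAF, the lineage allele-track TSV, one
#' BED per annotation track, the ground-truth TSV and the configuration YAML.
#' All files round-trip through the package's readers.
#'
#' @param sim a [simulate_dataset()] result.
#' @param outdir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_fixture <- function(sim, outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  paths <- c(
    alignment_fasta = file.path(outdir, "alignment.fa"),
    alignment_maf = file.path(outdir, "alignment.maf"),
    truth = file.path(outdir, "truth.tsv"),
    tracks = file.path(outdir, "lineage_tracks.tsv"),
    config = file.path(outdir, "config.yaml"))
  write_alignment_fasta(sim$alignment, paths["alignment_fasta"])
  write_maf(sim$alignment, paths["alignment_maf"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(sim$tracks, paths["tracks"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  for (lab in names(sim$annotations)) {
    p <- file.path(outdir, paste0(lab, ".bed"))
    write_bed(sim$annotations[[lab]], p)
    paths[paste0("bed_", lab)] <- p
  }
  cfg <- sim$config
  cfg$a3g_event_size <- as.list(cfg$a3g_event_size)
  cfg$branch_rates <- as.list(cfg$branch_rates)
  cfg$lineage_proportions <- as.list(cfg$lineage_proportions)
  yaml::write_yaml(unclass(cfg), paths["config"])
  invisible(paths)
}
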