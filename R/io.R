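#' Write sequences as 60-column wrapped FASTA
#' @param seqs named character vector
#' @param path output file
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path,
                              width = 60)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path FASTA file
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Write ground-truth annotations of a simulated genome as GFF3
#'
#' Copies become LTR_retrotransposon features; sub-features keep their SO-ish
#' types (long_terminal_repeat, primer_binding_site, RR_tract, ORF). Internal
#' 0-based half-open coordinates convert to 1-based inclusive on output.
#'
#' @param sim `sim_genome` object
#' @param path output GFF3 file
#' @export
write_truth_gff3 <- function(sim, path) {
  cp <- sim$truth$copies
  ft <- sim$truth$features
  gr_cp <- GenomicRanges::GRanges(
    seqnames = cp$contig,
    ranges = IRanges::IRanges(cp$start + 1L, cp$end),
    strand = cp$strand, type = "LTR_retrotransposon", ID = cp$copy_id)
  feat_type <- ifelse(ft$feature == "domain", "polypeptide_domain",
                      ft$feature)
  gr_ft <- GenomicRanges::GRanges(
    seqnames = "chr1",
    ranges = IRanges::IRanges(ft$start + 1L, ft$end),
    strand = ft$strand, type = feat_type,
    ID = paste0(ft$copy_id, ":", ft$label))
  rtracklayer::export(c(gr_cp, gr_ft), path, format = "gff3")
  invisible(path)
}

#' Write hits as BED6 (score = bits x 100, integer)
#' @param hits `rt_hits` data.frame
#' @param path output BED file
#' @export
write_hits_bed <- function(hits, path) {
  bed <- data.frame(chrom = hits$contig, start = hits$start, end = hits$end,
                    name = hits$best_profile,
                    score = as.integer(round(hits$best_score * 100)),
                    strand = hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write consensus records as FASTA with `species|cluster|n=` headers
#' @param consensuses list of `consensus_record`
#' @param path output file
#' @export
write_consensus_fasta <- function(consensuses, path) {
  seqs <- setNames(vapply(consensuses, `[[`, character(1), "seq"),
                   vapply(consensuses, `[[`, character(1), "consensus_id"))
  write_fasta(seqs, path)
}

#' Write a domain report as TSV (wide) plus a long format for plotting
#' @param report `domain_report`
#' @param path output TSV (wide filtered matrix); the long unfiltered table
#'   goes to `<path>.long.tsv`
#' @export
write_report_tsv <- function(report, path) {
  wide <- as.data.frame.matrix(report$filtered)
  wide <- cbind(species = rownames(wide), wide)
  write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  un <- report$unfiltered
  if (length(un)) {
    long <- as.data.frame(as.table(un), stringsAsFactors = FALSE)
    names(long) <- c("species", "domain_family", "n_consensuses")
    long <- long[long$n_consensuses > 0, , drop = FALSE]
    long$passes_filter <- long$n_consensuses >= report$min_consensuses
    write.table(long, paste0(path, ".long.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}

#' Write / read a genome simulation spec as YAML
#' @param spec `genome_spec`
#' @param path YAML file
#' @export
write_genome_spec <- function(spec, path) {
  x <- unclass(spec)
  x$elements <- lapply(x$elements, unclass)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_genome_spec
#' @export
read_genome_spec <- function(path) {
  x <- yaml::read_yaml(path)
  x$elements <- lapply(x$elements, function(e) {
    e$orf_specs <- lapply(e$orf_specs, function(o) {
      o$cassettes <- as.character(unlist(o$cassettes))
      o
    })
    structure(e, class = "element_spec")
  })
  do.call(genome_spec, x[c("species_id", "genome_len", "elements", "gc",
                           "gap_runs", "seed", "min_spacing")])
}

#' Write a distance matrix in PHYLIP square format
#' @param dm labeled symmetric matrix
#' @param path output file
#' @export
write_distance_phylip <- function(dm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste0(formatC(rownames(dm)[i], width = -10),
                      paste(sprintf("%.6f", dm[i, ]), collapse = " ")), con)
  }
  invisible(path)
}
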