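#' Build a consensus library for one species genome
#'
#' Runs the full discovery chain: RT profile scan over six-frame translations,
#' size filter, per-species 95%-identity clustering with a 50-sequence cap,
#' +/- 5 kb locus extension, coverage clustering, per-cluster progressive
#' alignment, and match-ratio consensus calling for clusters of at least
#' `min_members` loci.
#'
#' @param genome `sim_genome` or named character vector of contigs
#' @param library profile library from [generate_profile_library()]
#' @param species_id species label (taken from the `sim_genome` when absent)
#' @param score_threshold RT scan threshold (bits)
#' @param min_nt,max_nt RT size range (nt, inclusive)
#' @param id_threshold,cap per-species RT identity clustering parameters
#' @param flank locus extension per side (nt)
#' @param min_cov,min_identity locus clustering parameters
#' @param min_members minimum cluster size for a consensus
#' @param match_ratio consensus match-column ratio
#' @param band alignment band half-width
#' @return list of `consensus_record` objects (may be empty)
#' @export
discover_consensuses <- function(genome, library, species_id = NA,
                                 score_threshold = 30, min_nt = 520,
                                 max_nt = 840, id_threshold = 0.95, cap = 50,
                                 flank = 5000, min_cov = 0.5,
                                 min_identity = 0.8, min_members = 5,
                                 match_ratio = 0.5, band = 512) {
  if (inherits(genome, "sim_genome") && is.na(species_id))
    species_id <- genome$spec$species_id
  fasta <- if (inherits(genome, "sim_genome")) genome$fasta else genome
  rt_profiles <- Filter(function(p) p$family == "RT", library$profiles)
  hits <- scan_rt(fasta, rt_profiles, threshold = score_threshold,
                  species_id = species_id)
  hits <- filter_size(hits, min_nt, max_nt)
  if (!nrow(hits)) return(list())
  rownames(hits) <- NULL
  hit_ids <- paste0("rt", seq_len(nrow(hits)))
  rt_seqs <- setNames(vapply(seq_len(nrow(hits)), function(i) {
    s <- substr(fasta[[hits$contig[i]]], hits$start[i] + 1L, hits$end[i])
    if (hits$strand[i] == "-") s <- revcomp(s)
    s
  }, character(1)), hit_ids)
  cl <- cluster_identity(rt_seqs, threshold = id_threshold, cap = cap)
  selected <- unlist(lapply(cl, `[[`, "reported"))
  hits <- hits[match(selected, hit_ids), , drop = FALSE]
  loci <- extend_loci(hits, fasta, flank = flank)
  clusters <- cluster_loci(loci, min_cov = min_cov,
                           min_identity = min_identity,
                           min_members = min_members)
  out <- list()
  ci <- 0L
  for (clu in clusters) {
    if (!clu$eligible) next
    ci <- ci + 1L
    ids <- head(clu$members, 50)
    seqs <- setNames(loci$seq[match(ids, loci$locus_id)], ids)
    msa <- align_cluster(seqs, band = band)
    cid <- paste0(species_id, "|cluster", ci, "|n=", length(ids))
    out[[length(out) + 1L]] <- consensus_from_msa(
      msa, match_ratio = match_ratio, species_id = species_id,
      consensus_id = cid)
  }
  out
}

#' Annotate consensus records and build the fixation report
#'
#' Scans every consensus for all library profiles, classifies its
#' superfamily, collapses redundant profile hits, removes canonical domain
#' families, and assembles the n-filter domain x species report.
#'
#' @param consensuses list of `consensus_record` objects
#' @param library profile library (profiles + rt_refs)
#' @param threshold domain scan threshold (bits)
#' @param family_map optional label -> representative collapse map
#' @param min_consensuses fixation threshold for the report
#' @return list: `hits` (all domain hits), `noncanonical` (collapsed,
#'   canonical-filtered hits), `report` (`domain_report`), `superfamilies`
#'   (data.frame consensus_id, label, best_score, margin)
#' @export
annotate_consensuses <- function(consensuses, library, threshold = 30,
                                 family_map = character(0),
                                 min_consensuses = 5) {
  hits <- do.call(rbind, lapply(consensuses, scan_domains,
                                profiles = library$profiles,
                                threshold = threshold))
  if (is.null(hits)) hits <- scan_domains("", library$profiles)
  sfs <- do.call(rbind, lapply(consensuses, function(cs) {
    call <- classify_superfamily(cs, library$rt_refs, library$profiles,
                                 threshold = threshold)
    data.frame(consensus_id = call$consensus_id, label = call$label,
               best_score = call$best_score, margin = call$margin,
               stringsAsFactors = FALSE)
  }))
  if (is.null(sfs)) sfs <- data.frame(consensus_id = character(0),
                                      label = character(0))
  noncanon <- filter_canonical(collapse_profile_families(hits, family_map))
  report <- n_filter_report(noncanon, min_consensuses = min_consensuses)
  list(hits = hits, noncanonical = noncanon, report = report,
       superfamilies = sfs)
}
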