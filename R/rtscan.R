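#' Six-frame translation of a nucleotide sequence
#'
#' Standard genetic code; codons containing N (or other ambiguity codes)
#' translate to X, stops to `*`. Reverse-strand frames are the forward
#' translation of the reverse complement.
#'
#' @param seq DNA string over A/C/G/T/N
#' @return data.frame with columns `strand` ("+"/"-"), `frame` (1-3) and `aa`
#' @export
six_frame_translate <- function(seq) {
  translate_frames <- function(s) {
    vapply(1:3, function(f) {
      n <- nchar(s) - f + 1L
      n <- n - n %% 3L
      if (n < 3L) return("")
      as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, f, f + n - 1L)),
        if.fuzzy.codon = "X"))
    }, character(1))
  }
  fwd <- translate_frames(seq)
  rev <- translate_frames(revcomp(seq))
  data.frame(strand = rep(c("+", "-"), each = 3), frame = rep(1:3, 2),
             aa = c(fwd, rev), stringsAsFactors = FALSE)
}

# project an aa window hit back to forward-strand nucleotide coordinates
# (0-based half-open). p is the 1-based window start on the translated frame.
aa_window_to_nt <- function(p, L, frame, strand, contig_len) {
  s0 <- (frame - 1L) + 3L * (p - 1L)
  e0 <- s0 + 3L * L
  if (strand == "+") c(s0, e0) else c(contig_len - e0, contig_len - s0)
}

#' Scan a genome for RT (or any) profile matches over six-frame translations
#'
#' Slides each amino-acid PSSM over every translated frame of every contig;
#' windows scoring at or above the threshold are projected to nucleotide
#' coordinates and overlapping projections are merged into single hits,
#' keeping the best score and its profile.
#'
#' @param genome named character vector of contig sequences, or a `sim_genome`
#' @param profiles list of profile objects (label, family, pssm)
#' @param threshold minimum window score in bits
#' @param species_id species label attached to the hits
#' @return data.frame of class `rt_hits`: species_id, contig, start, end
#'   (0-based half-open), strand, best_score, best_profile
#' @export
scan_rt <- function(genome, profiles, threshold = 30, species_id = NA) {
  if (inherits(genome, "sim_genome")) {
    if (is.na(species_id)) species_id <- genome$spec$species_id
    genome <- genome$fasta
  }
  raw <- list()
  for (contig in names(genome)) {
    seq <- genome[[contig]]
    clen <- nchar(seq)
    frames <- six_frame_translate(seq)
    for (i in seq_len(nrow(frames))) {
      aa_int <- aa_to_int(frames$aa[i])
      for (pr in profiles) {
        L <- nrow(pr$pssm)
        r <- pssm_scan_cpp(aa_int, pr$pssm, threshold, 0, -4)
        if (!length(r$pos)) next
        nt <- t(vapply(r$pos, aa_window_to_nt, numeric(2), L = L,
                       frame = frames$frame[i], strand = frames$strand[i],
                       contig_len = clen))
        raw[[length(raw) + 1L]] <- data.frame(
          contig = contig, start = nt[, 1], end = nt[, 2],
          strand = frames$strand[i], score = r$score, profile = pr$label,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(raw)) {
    out <- data.frame(species_id = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), best_score = numeric(0),
                      best_profile = character(0))
    class(out) <- c("rt_hits", "data.frame")
    return(out)
  }
  raw <- do.call(rbind, raw)
  out <- merge_hits(raw)
  out <- data.frame(species_id = species_id, out, stringsAsFactors = FALSE)
  class(out) <- c("rt_hits", "data.frame")
  out
}

#' Merge overlapping hit intervals per contig, keeping the maximum score
#'
#' Merging is idempotent: merging already-merged hits is a no-op.
#' @param raw data.frame with contig, start, end, strand, score, profile
#' @return merged data.frame with best_score/best_profile per interval
#' @export
merge_hits <- function(raw) {
  out <- lapply(split(raw, raw$contig), function(d) {
    ir <- IRanges::IRanges(start = d$start + 1L, end = d$end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    idx <- S4Vectors::mcols(red)$revmap
    best <- vapply(idx, function(ii) ii[which.max(d$score[ii])], integer(1))
    data.frame(contig = d$contig[1], start = IRanges::start(red) - 1L,
               end = IRanges::end(red), strand = d$strand[best],
               best_score = d$score[best], best_profile = d$profile[best],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Keep hits whose merged span falls in the expected RT size range
#'
#' Bounds are inclusive on both sides.
#' @param hits `rt_hits` data.frame
#' @param min_nt,max_nt inclusive span bounds in nucleotides
#' @export
filter_size <- function(hits, min_nt = 520, max_nt = 840) {
  w <- hits$end - hits$start
  hits[w >= min_nt & w <= max_nt, , drop = FALSE]
}

#' Global alignment identity between two sequences
#'
#' Needleman-Wunsch with match 1 / mismatch -1 / gap open -5 / extend -1;
#' identity is matches over total alignment columns, so gaps count against
#' identity.
#'
#' @param a,b DNA strings (set `aa = TRUE` for amino acids, scored with
#'   identity match/mismatch as well)
#' @param aa logical; treat inputs as amino-acid sequences
#' @return identity fraction in [0, 1]
#' @export
global_identity <- function(a, b, aa = FALSE) {
  if (is.null(the$nt_submat)) {
    the$nt_submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  }
  if (aa) {
    letters_aa <- c(AA20, "X", "*")
    sm <- matrix(-1, length(letters_aa), length(letters_aa),
                 dimnames = list(letters_aa, letters_aa))
    diag(sm) <- 1
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = sm, gapOpening = 4, gapExtension = 1,
      type = "global")
  } else {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b),
      substitutionMatrix = the$nt_submat, gapOpening = 4, gapExtension = 1,
      type = "global")
  }
  alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
  Biostrings::nmatch(aln) / alen
}

#' Greedy incremental identity clustering with a per-cluster reporting cap
#'
#' Sequences are sorted by length descending (ties by id); each sequence joins
#' the first existing representative it matches at or above the identity
#' threshold (global alignment identity), otherwise it founds a new cluster.
#' Each cluster reports at most `cap` members, longest first.
#'
#' @param seqs named character vector of sequences
#' @param threshold global identity threshold in [0, 1]
#' @param cap maximum reported members per cluster (Inf to disable)
#' @return list of class `identity_clusters`; each element has
#'   `representative`, `members` (all ids) and `reported` (capped ids)
#' @export
cluster_identity <- function(seqs, threshold = 0.95, cap = 50) {
  if (!length(seqs)) return(structure(list(), class = "identity_clusters"))
  ord <- order(-nchar(seqs), names(seqs))
  seqs <- seqs[ord]
  reps <- character(0)
  members <- list()
  for (id in names(seqs)) {
    joined <- FALSE
    for (r in seq_along(reps)) {
      if (global_identity(seqs[[id]], seqs[[reps[r]]]) >= threshold) {
        members[[r]] <- c(members[[r]], id)
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, id)
      members[[length(reps)]] <- id
    }
  }
  out <- lapply(seq_along(reps), function(r) {
    list(representative = reps[r], members = members[[r]],
         reported = head(members[[r]], cap),
         identity_threshold = threshold)
  })
  structure(out, class = "identity_clusters")
}

#' Extend RT hits into loci and extract their sequences
#'
#' Intervals grow by `flank` nucleotides on each side, clamped at contig
#' bounds; minus-strand loci are reverse-complemented so every locus reads in
#' element orientation.
#'
#' @param hits `rt_hits` data.frame
#' @param genome named character vector of contigs (or `sim_genome`)
#' @param flank extension per side (nt)
#' @return data.frame of class `extended_loci`: locus_id, species_id, contig,
#'   start, end (0-based half-open), strand, seq
#' @export
extend_loci <- function(hits, genome, flank = 5000) {
  if (inherits(genome, "sim_genome")) genome <- genome$fasta
  rows <- lapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    if (!h$contig %in% names(genome))
      stop("contig '", h$contig, "' not found in genome")
    clen <- nchar(genome[[h$contig]])
    s <- max(0L, h$start - flank)
    e <- min(clen, h$end + flank)
    seq <- substr(genome[[h$contig]], s + 1L, e)
    if (h$strand == "-") seq <- revcomp(seq)
    data.frame(locus_id = paste0(h$species_id, "|", h$contig, "|", s, "-", e,
                                 "|", h$strand),
               species_id = h$species_id, contig = h$contig, start = s,
               end = e, strand = h$strand, seq = seq, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(locus_id = character(0))
  class(out) <- c("extended_loci", "data.frame")
  out
}
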