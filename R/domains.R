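#' Scan a consensus sequence for protein domains
#'
#' Six-frame translation followed by the same windowed PSSM engine used for
#' RT discovery; overlapping hits of the same profile family are merged,
#' keeping the best score.
#'
#' @param consensus a `consensus_record`, or a bare nt string
#' @param profiles profile library list (label, family, canonical, pssm)
#' @param threshold minimum window score (bits)
#' @return data.frame of class `domain_hits`: consensus_id, species_id,
#'   label, family, canonical, strand, frame, aa_start, aa_end (1-based,
#'   inclusive, on the translated frame), score
#' @export
scan_domains <- function(consensus, profiles, threshold = 30) {
  if (inherits(consensus, "consensus_record")) {
    seq <- consensus$seq
    cid <- consensus$consensus_id
    sp <- consensus$species_id
  } else {
    seq <- consensus
    cid <- NA
    sp <- NA
  }
  empty <- data.frame(consensus_id = character(0), species_id = character(0),
                      label = character(0), family = character(0),
                      canonical = logical(0), strand = character(0),
                      frame = integer(0), aa_start = integer(0),
                      aa_end = integer(0), score = numeric(0))
  class(empty) <- c("domain_hits", "data.frame")
  if (!nzchar(seq)) return(empty)
  frames <- six_frame_translate(seq)
  rows <- list()
  for (i in seq_len(nrow(frames))) {
    if (!nzchar(frames$aa[i])) next
    aa_int <- aa_to_int(frames$aa[i])
    for (pr in profiles) {
      r <- pssm_scan_cpp(aa_int, pr$pssm, threshold, 0, -4)
      if (!length(r$pos)) next
      rows[[length(rows) + 1L]] <- data.frame(
        consensus_id = cid, species_id = sp, label = pr$label,
        family = pr$family, canonical = isTRUE(pr$canonical),
        strand = frames$strand[i], frame = frames$frame[i],
        aa_start = r$pos, aa_end = r$pos + nrow(pr$pssm) - 1L,
        score = r$score, stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  hits <- do.call(rbind, rows)
  # merge overlapping same-family hits (same frame/strand), keep max score
  keyed <- split(hits, list(hits$family, hits$strand, hits$frame),
                 drop = TRUE)
  merged <- lapply(keyed, function(d) {
    ir <- IRanges::IRanges(start = d$aa_start, end = d$aa_end)
    red <- IRanges::reduce(ir, with.revmap = TRUE)
    idx <- S4Vectors::mcols(red)$revmap
    best <- vapply(idx, function(ii) ii[which.max(d$score[ii])], integer(1))
    out <- d[best, , drop = FALSE]
    out$aa_start <- IRanges::start(red)
    out$aa_end <- IRanges::end(red)
    out
  })
  out <- do.call(rbind, merged)
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("domain_hits", "data.frame")
  out
}

#' Classify a consensus into an LTR-retrotransposon superfamily
#'
#' Finds the RT region on the translated consensus (best RT-family profile
#' hit), then local-aligns it against every labeled reference RT sequence;
#' the superfamily of the best-scoring reference wins. Ties are broken toward
#' the earlier label in the fixed ordering Copia, Gypsy, DIRS, ERV,
#' Caulimoviridae, LINE and flagged; a margin below 1 is flagged ambiguous.
#'
#' @param consensus `consensus_record` or nt string
#' @param rt_refs named character vector of reference RT aa sequences with a
#'   `superfamily` attribute (see [generate_profile_library()])
#' @param profiles profile library (used to locate the RT region)
#' @param threshold scan threshold for the RT region search
#' @return list of class `superfamily_call`: consensus_id, label, best_score,
#'   margin, ambiguous
#' @export
classify_superfamily <- function(consensus, rt_refs, profiles,
                                 threshold = 30) {
  ordering <- c("Copia", "Gypsy", "DIRS", "ERV", "Caulimoviridae", "LINE")
  cid <- if (inherits(consensus, "consensus_record"))
    consensus$consensus_id else NA
  rt_profiles <- Filter(function(p) p$family == "RT", profiles)
  hits <- scan_domains(consensus, rt_profiles, threshold)
  if (!nrow(hits)) {
    return(structure(list(consensus_id = cid, label = "unclassified",
                          best_score = NA_real_, margin = NA_real_,
                          ambiguous = FALSE), class = "superfamily_call"))
  }
  best_hit <- hits[1, ]
  seq <- if (inherits(consensus, "consensus_record")) consensus$seq else
    consensus
  frames <- six_frame_translate(seq)
  aa <- frames$aa[frames$strand == best_hit$strand &
                  frames$frame == best_hit$frame]
  region <- substr(aa, best_hit$aa_start, best_hit$aa_end)

  sf <- attr(rt_refs, "superfamily")
  scores <- vapply(names(rt_refs), function(id) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(gsub("[^A-Z]", "X", region)),
      Biostrings::AAString(rt_refs[[id]]),
      substitutionMatrix = aa_identity_matrix(), gapOpening = 4,
      gapExtension = 1, type = "local")
    Biostrings::score(aln)
  }, numeric(1))
  by_sf <- tapply(scores, sf[names(scores)], max)
  by_sf <- by_sf[order(-by_sf, match(names(by_sf), ordering))]
  label <- names(by_sf)[1]
  margin <- if (length(by_sf) > 1) by_sf[[1]] - by_sf[[2]] else Inf
  structure(list(consensus_id = cid, label = label,
                 best_score = unname(by_sf[[1]]), margin = margin,
                 ambiguous = margin < 1), class = "superfamily_call")
}

aa_identity_matrix <- function() {
  if (is.null(the$aa_submat)) {
    letters_aa <- c(AA20, "X", "*")
    sm <- matrix(-1, length(letters_aa), length(letters_aa),
                 dimnames = list(letters_aa, letters_aa))
    diag(sm) <- 2
    sm["X", ] <- 0; sm[, "X"] <- 0
    the$aa_submat <- sm
  }
  the$aa_submat
}

#' Remove hits to canonical LTR-retrotransposon domain families
#'
#' @param hits `domain_hits` data.frame
#' @param canonical_families families considered canonical
#' @return hits whose family is outside the canonical set
#' @export
filter_canonical <- function(hits,
                             canonical_families = c("GAG", "PR", "RT",
                                                    "RNaseH", "INT",
                                                    "Chromo")) {
  hits[!hits$family %in% canonical_families, , drop = FALSE]
}

#' Collapse hits against homologous profiles to one representative per family
#'
#' @param hits `domain_hits` data.frame
#' @param family_map named character vector mapping profile label to a family
#'   representative; unmapped labels pass through under their own name
#' @return collapsed `domain_hits` (one hit per consensus x representative,
#'   max score)
#' @export
collapse_profile_families <- function(hits, family_map = character(0)) {
  if (!nrow(hits)) return(hits)
  rep_lab <- ifelse(hits$label %in% names(family_map),
                    unname(family_map[hits$label]), hits$label)
  unmapped <- setdiff(unique(hits$label), names(family_map))
  if (length(family_map) && length(unmapped))
    message("unmapped profile labels pass through: ",
            paste(unmapped, collapse = ", "))
  hits$family <- ifelse(hits$label %in% names(family_map),
                        rep_lab, hits$family)
  hits$label <- rep_lab
  key <- paste(hits$consensus_id, hits$label)
  keep <- unlist(lapply(split(seq_len(nrow(hits)), key), function(ii)
    ii[which.max(hits$score[ii])]))
  out <- hits[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the domain x species fixation report (the n-filter report)
#'
#' Counts, per (species, domain family), the number of distinct consensus
#' sequences carrying the domain. Cells with a count at or above
#' `min_consensuses` pass the filter. Both the filtered and unfiltered views
#' are returned; setting `min_consensuses = 1` reproduces the no-filter view.
#'
#' @param hits `domain_hits` rows tagged with species_id and consensus_id
#' @param min_consensuses fixation threshold (the "n5" filter at its default)
#' @return list of class `domain_report`: `filtered` and `unfiltered`
#'   species x family integer matrices, plus `min_consensuses`
#' @export
n_filter_report <- function(hits, min_consensuses = 5) {
  if (!nrow(hits)) {
    m <- matrix(integer(0), 0, 0)
    return(structure(list(filtered = m, unfiltered = m,
                          min_consensuses = min_consensuses),
                     class = "domain_report"))
  }
  u <- unique(hits[, c("species_id", "family", "consensus_id")])
  tab <- table(u$species_id, u$family)
  unfiltered <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                       dimnames = dimnames(tab))
  filtered <- unfiltered
  filtered[filtered < min_consensuses] <- 0L
  filtered <- filtered[rowSums(filtered) > 0, colSums(filtered) > 0,
                       drop = FALSE]
  structure(list(filtered = filtered, unfiltered = unfiltered,
                 min_consensuses = min_consensuses),
            class = "domain_report")
}

#' Check AlkB-family cofactor-binding motifs in a 2-ODD amino-acid sequence
#'
#' Reports (i) the iron-coordinating HxD/E motif with a distal H within a
#' configurable downstream span, (ii) the 2-OG-stabilizing RxxxxxR motif,
#' (iii) the m6A-recognition YNF motif, and optionally (iv) the N/Y
#' 2-OG-stabilizing pair read off an alignment to a reference ALKBH5-style
#' block with known N/Y positions.
#'
#' @param aa amino-acid sequence of the 2-ODD region
#' @param distal_h_span downstream distance range (residues) in which the
#'   distal H of the iron core must occur
#' @param reference optional list(block = aa string, n_pos =, y_pos =) giving
#'   a reference block and the 1-based positions of the N and Y residues
#' @return list of class `motif_record` with elements `iron_core`,
#'   `r_x5_r`, `ynf` (each NULL or 1-based position info) and `ny_pair`
#' @export
check_cofactor_motifs <- function(aa, distal_h_span = c(30, 90),
                                  reference = NULL) {
  out <- list(iron_core = NULL, r_x5_r = NULL, ynf = NULL, ny_pair = NULL)
  n <- nchar(aa)
  if (n >= 3) {
    m <- gregexpr("H.[DE]", aa)[[1]]
    if (m[1] != -1) {
      for (p in as.integer(m)) {
        lo <- p + distal_h_span[1]; hi <- min(n, p + distal_h_span[2])
        if (lo <= n) {
          window <- substr(aa, lo, hi)
          hrel <- regexpr("H", window, fixed = TRUE)
          if (hrel != -1) {
            out$iron_core <- list(hxd_pos = p,
                                  distal_h_pos = lo + as.integer(hrel) - 1L)
            break
          }
        }
      }
    }
    m2 <- regexpr("R.{5}R", aa)
    if (m2 != -1) out$r_x5_r <- list(pos = as.integer(m2))
    m3 <- regexpr("YNF", aa, fixed = TRUE)
    if (m3 != -1) out$ynf <- list(pos = as.integer(m3))
  }
  if (!is.null(reference)) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(aa), Biostrings::AAString(reference$block),
      substitutionMatrix = aa_identity_matrix(), gapOpening = 4,
      gapExtension = 1, type = "local")
    pat <- split1(as.character(Biostrings::alignedPattern(aln)))
    sub <- split1(as.character(Biostrings::alignedSubject(aln)))
    sub_pos <- cumsum(sub != "-") + Biostrings::start(
      Biostrings::subject(aln)) - 1L
    n_res <- pat[match(reference$n_pos, sub_pos)]
    y_res <- pat[match(reference$y_pos, sub_pos)]
    out$ny_pair <- list(n_conserved = identical(n_res, "N"),
                        y_conserved = identical(y_res, "Y"),
                        residues = c(n_res, y_res))
  }
  structure(out, class = "motif_record")
}

#' Scan for K/R-rich basic patches (disordered-region proxy)
#'
#' Sliding-window fraction of lysine + arginine; maximal runs of windows at or
#' above the threshold are merged into intervals.
#'
#' @param aa amino-acid sequence
#' @param window window length (residues)
#' @param kr_fraction minimum K+R fraction per window
#' @return data.frame with 1-based inclusive `start`, `end` and the peak
#'   window fraction per interval (zero rows when none)
#' @export
scan_basic_patch <- function(aa, window = 25, kr_fraction = 0.4) {
  n <- nchar(aa)
  empty <- data.frame(start = integer(0), end = integer(0),
                      max_fraction = numeric(0))
  if (n < window) return(empty)
  iskr <- as.integer(split1(aa) %in% c("K", "R"))
  cs <- c(0, cumsum(iskr))
  frac <- (cs[(window + 1):(n + 1)] - cs[1:(n - window + 1)]) / window
  hit <- frac >= kr_fraction
  if (!any(hit)) return(empty)
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- data.frame(
    start = starts[keep],
    end = ends[keep] + window - 1L,
    max_fraction = vapply(keep, function(k)
      max(frac[starts[k]:ends[k]]), numeric(1)))
  rownames(out) <- NULL
  out
}
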