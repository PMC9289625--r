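#' Detect LTR pairs on a contig by exact-seed chaining and extension
#'
#' Exact k-mer matches between positions whose offset lies in
#' `[min_dist, max_dist]` (the offset between LTR start positions) nominate
#' candidate direct-repeat pairs. For each candidate offset the per-position
#' match vector between the two copies is extended outward from the seed span
#' (match +1 / mismatch -3, boundary at the running-score maximum). Boundaries
#' are then snapped to canonical TG...CA termini when both copies agree
#' within `motif_slack` nt. Candidates are kept when the repeat length lies in
#' `[min_ltr_len, max_ltr_len]` and identity is at least `min_ltr_identity`;
#' overlapping candidates resolve to the highest identity x length.
#'
#' @param seq contig DNA string
#' @param min_dist,max_dist allowed offset between LTR start positions (nt)
#' @param max_ltr_len,min_ltr_len allowed repeat length (nt)
#' @param min_ltr_identity minimum identity between the two repeat copies
#' @param k exact seed length
#' @param min_seeds minimum seeds supporting an offset
#' @param motif_slack search slack for TG...CA boundary snapping (nt)
#' @return data.frame of class `element_models` with 0-based half-open
#'   columns: start, end (element interval), ltr5_start, ltr5_end,
#'   ltr3_start, ltr3_end, ltr_len, ltr_identity
#' @export
find_ltr_pairs <- function(seq, min_dist = 5000, max_dist = 20000,
                           max_ltr_len = 3000, min_ltr_identity = 0.85,
                           min_ltr_len = 100, k = 20, min_seeds = 2,
                           motif_slack = 5) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      ltr5_start = integer(0), ltr5_end = integer(0),
                      ltr3_start = integer(0), ltr3_end = integer(0),
                      ltr_len = integer(0), ltr_identity = numeric(0))
  class(empty) <- c("element_models", "data.frame")
  n <- nchar(seq)
  if (n < min_dist + k) return(empty)

  pairs <- seed_pairs(seq, k, min_dist, max_dist)
  if (!nrow(pairs)) return(empty)

  sraw <- utf8ToInt(seq)
  cands <- list()
  for (delta in unique(pairs$delta)) {
    seeds <- pairs$i[pairs$delta == delta]
    if (length(seeds) < min_seeds) next
    m <- sraw[seq_len(n - delta)] == sraw[(delta + 1):n]
    # seeds may span several repeats at the same offset; split on big gaps
    seeds <- sort(seeds)
    grp <- cumsum(c(1, diff(seeds) > max_ltr_len))
    for (g in unique(grp)) {
      ss <- seeds[grp == g]
      s0 <- min(ss); e0 <- min(max(ss) + k - 1L, length(m))
      b <- extend_repeat(m, s0, e0, max_ltr_len)
      b <- snap_motif(seq, b, delta, motif_slack, n)
      len <- b[2] - b[1] + 1L
      ident <- mean(m[b[1]:b[2]])
      if (len >= min_ltr_len && len <= max_ltr_len &&
          ident >= min_ltr_identity) {
        cands[[length(cands) + 1L]] <- data.frame(
          start = b[1] - 1L, end = b[2] + delta,
          ltr5_start = b[1] - 1L, ltr5_end = b[2],
          ltr3_start = b[1] - 1L + delta, ltr3_end = b[2] + delta,
          ltr_len = len, ltr_identity = ident)
      }
    }
  }
  if (!length(cands)) return(empty)
  out <- do.call(rbind, cands)
  # resolve overlaps by identity x length; near-ties (identity rounded to
  # 2 dp) prefer the more compact element, so an intra-element pair beats a
  # cross-element pairing of equally similar LTRs
  out <- out[order(-(round(out$ltr_identity, 2) * out$ltr_len),
                   out$end - out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    later <- which(keep & seq_len(nrow(out)) > i)
    ov <- pmax(out$start[later], out$start[i]) <
      pmin(out$end[later], out$end[i])
    keep[later[ov]] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("element_models", "data.frame")
  out
}

# all same-word position pairs (i < j) with offset in [min_dist, max_dist];
# returns data.frame(i, delta), 1-based i
seed_pairs <- function(seq, k, min_dist, max_dist) {
  n <- nchar(seq)
  pos <- seq_len(n - k + 1L)
  words <- substring(seq, pos, pos + k - 1L)
  o <- order(words, method = "radix")
  w <- words[o]
  r <- rle(w)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out_i <- integer(0); out_d <- integer(0)
  multi <- which(r$lengths > 1 & r$lengths <= 200 &
                 !grepl("N", r$values, fixed = TRUE))
  for (idx in multi) {
    p <- sort(pos[o[starts[idx]:ends[idx]]])
    cmb <- utils::combn(p, 2)
    d <- cmb[2, ] - cmb[1, ]
    okp <- d >= min_dist & d <= max_dist
    out_i <- c(out_i, cmb[1, okp]); out_d <- c(out_d, d[okp])
  }
  data.frame(i = out_i, delta = out_d)
}

# extend the repeat run outward from [s0, e0] on the match vector m,
# boundary at the running-score maximum (match +1 / mismatch -3)
extend_repeat <- function(m, s0, e0, max_span) {
  lo <- max(1L, s0 - max_span)
  if (s0 > lo) {
    f <- ifelse(m[(s0 - 1L):lo], 1, -3) # walking left
    cs <- cumsum(f)
    best <- which.max(cs)
    if (cs[best] > 0) s0 <- s0 - best
  }
  hi <- min(length(m), e0 + max_span)
  if (e0 < hi) {
    f <- ifelse(m[(e0 + 1L):hi], 1, -3)
    cs <- cumsum(f)
    best <- which.max(cs)
    if (cs[best] > 0) e0 <- e0 + best
  }
  c(s0, e0)
}

# snap boundaries to TG...CA termini; candidates supported by both repeat
# copies win, with a single-copy fallback (the motif may be mutated in one
# copy of a diverged pair)
snap_motif <- function(seq, b, delta, slack, n) {
  s0 <- b[1]; e0 <- b[2]
  cand <- (s0 - slack):(s0 + slack)
  cand <- cand[cand >= 1 & cand + delta + 1 <= n]
  tg5 <- substring(seq, cand, cand + 1) == "TG"
  tg3 <- substring(seq, cand + delta, cand + delta + 1) == "TG"
  hit <- cand[tg5 & tg3]
  if (!length(hit)) hit <- cand[tg5 | tg3]
  if (length(hit)) s0 <- hit[which.min(abs(hit - b[1]))]
  cand <- (e0 - slack):(e0 + slack)
  cand <- cand[cand >= 2 & cand + delta <= n]
  ca5 <- substring(seq, cand - 1, cand) == "CA"
  ca3 <- substring(seq, cand - 1 + delta, cand + delta) == "CA"
  hit <- cand[ca5 & ca3]
  if (!length(hit)) hit <- cand[ca5 | ca3]
  if (length(hit)) e0 <- hit[which.min(abs(hit - b[2]))]
  if (e0 > s0) c(s0, e0) else b
}

#' Terminal inverted repeat length of an LTR
#'
#' Longest prefix (within `[min_tir, max_tir]`) whose reverse complement
#' equals the LTR suffix; 0 when none.
#' @param ltr_seq LTR DNA string (at least 2*max_tir long)
#' @param max_tir,min_tir length bounds
#' @export
detect_tir <- function(ltr_seq, max_tir = 12, min_tir = 3) {
  n <- nchar(ltr_seq)
  stopifnot(n >= 2 * max_tir)
  for (L in seq(max_tir, min_tir)) {
    if (revcomp(substr(ltr_seq, 1, L)) == substr(ltr_seq, n - L + 1, n))
      return(L)
  }
  0L
}

#' Find ORFs on both strands of a sequence
#'
#' Maximal ATG-to-stop spans per frame (or any-start spans after the previous
#' stop with `any_start = TRUE`); reported amino-acid length excludes the
#' stop. Results are sorted by length descending.
#'
#' @param seq DNA string
#' @param min_aa minimum ORF length (aa)
#' @param any_start allow ORFs to start at any codon
#' @return data.frame: strand, frame, start, end (0-based half-open nt span
#'   on the forward strand, including the stop codon), aa_len, aa
#' @export
find_orfs <- function(seq, min_aa = 300, any_start = FALSE) {
  n <- nchar(seq)
  rows <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (f in 1:3) {
      m <- nchar(s) - f + 1L
      m <- m - m %% 3L
      if (m < 3L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, f, f + m - 1L)),
        if.fuzzy.codon = "X"))
      ch <- split1(aa)
      stops <- which(ch == "*")
      prev <- 0L
      for (st in stops) {
        block <- if (prev + 1L <= st - 1L) ch[(prev + 1L):(st - 1L)] else
          character(0)
        start_rel <- if (any_start) prev + 1L else {
          mm <- which(block == "M")
          if (!length(mm)) { prev <- st; next }
          prev + mm[1]
        }
        aa_len <- st - start_rel
        if (aa_len >= min_aa) {
          nt_s <- (f - 1L) + 3L * (start_rel - 1L)     # 0-based on s
          nt_e <- (f - 1L) + 3L * st                   # includes stop codon
          if (strand == "-") { tmp <- nt_s; nt_s <- n - nt_e; nt_e <- n - tmp }
          rows[[length(rows) + 1L]] <- data.frame(
            strand = strand, frame = f, start = nt_s, end = nt_e,
            aa_len = aa_len,
            aa = paste(ch[start_rel:(st - 1L)], collapse = ""),
            stringsAsFactors = FALSE)
        }
        prev <- st
      }
    }
  }
  if (!length(rows))
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      aa_len = integer(0), aa = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(-out$aa_len), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect the primer binding site just downstream of the 5' LTR
#'
#' Searches a window for the reverse complement of the 3'-terminal
#' `>= min_match` nt of any library tRNA; the best record is the longest
#' match, ties broken by proximity to the LTR.
#'
#' @param seq_downstream sequence immediately 3' of the 5' LTR
#' @param trna_library named character vector of tRNA sequences
#' @param window search window (nt)
#' @param min_match minimum matched tRNA 3' length (nt)
#' @param max_match maximum matched tRNA 3' length tried (nt)
#' @return list(trna, start, end, length) with 0-based half-open coordinates
#'   relative to `seq_downstream`, or NULL when absent
#' @export
detect_pbs <- function(seq_downstream, trna_library, window = 30,
                       min_match = 12, max_match = 18) {
  stopifnot(length(trna_library) > 0)
  region <- substr(seq_downstream, 1, window)
  best <- NULL
  for (lab in names(trna_library)) {
    trna <- trna_library[[lab]]
    for (L in seq(min(max_match, nchar(trna)), min_match)) {
      pat <- revcomp(substr(trna, nchar(trna) - L + 1L, nchar(trna)))
      p <- regexpr(pat, region, fixed = TRUE)
      if (p != -1) {
        rec <- list(trna = lab, start = as.integer(p) - 1L,
                    end = as.integer(p) - 1L + L, length = L)
        if (is.null(best) || rec$length > best$length ||
            (rec$length == best$length && rec$start < best$start))
          best <- rec
        break
      }
    }
  }
  best
}

#' Detect the polypurine tract just upstream of the 3' LTR
#'
#' Picks the run (length at least `min_len`) with the highest purine fraction
#' inside the window closest to the 3' LTR; ties go to the longer, then the
#' more LTR-proximal run.
#'
#' @param seq_upstream sequence immediately 5' of the 3' LTR
#' @param window window size examined at the 3' end of `seq_upstream`
#' @param min_len minimum run length (nt)
#' @param min_purine minimum purine (A/G) fraction
#' @return list(start, end, purine_fraction) 0-based half-open relative to
#'   `seq_upstream`, or NULL
#' @export
detect_ppt <- function(seq_upstream, window = 50, min_len = 10,
                       min_purine = 0.85) {
  n <- nchar(seq_upstream)
  off <- max(0L, n - window)
  region <- substr(seq_upstream, off + 1L, n)
  w <- nchar(region)
  if (w < min_len) return(NULL)
  pur <- as.integer(split1(region) %in% c("A", "G"))
  cs <- c(0, cumsum(pur))
  best <- NULL
  for (len in min_len:w) {
    for (s in 1:(w - len + 1L)) {
      frac <- (cs[s + len] - cs[s]) / len
      if (frac < min_purine) next
      better <- is.null(best) ||
        frac > best$purine_fraction ||
        (frac == best$purine_fraction &&
           (len > best$end - best$start ||
              (len == best$end - best$start && s - 1L + off > best$start)))
      if (better)
        best <- list(start = off + s - 1L, end = off + s - 1L + len,
                     purine_fraction = frac)
    }
  }
  best
}

#' Count non-overlapping RNase H domain copies on a polyprotein
#'
#' @param polyprotein_aa amino-acid string
#' @param rnaseh_profile profile object with a `pssm`
#' @param threshold minimum window score (bits)
#' @return integer copy count (greedy non-overlapping selection by score)
#' @export
detect_dual_rnaseh <- function(polyprotein_aa, rnaseh_profile,
                               threshold = 30) {
  hits <- score_pssm(polyprotein_aa, rnaseh_profile$pssm, threshold)
  if (!nrow(hits)) return(0L)
  L <- nrow(rnaseh_profile$pssm)
  hits <- hits[order(-hits$score), , drop = FALSE]
  taken <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(hits))) {
    s <- hits$pos[i]; e <- s + L - 1L
    if (!nrow(taken) || all(pmax(taken[, 1], s) > pmin(taken[, 2], e)))
      taken <- rbind(taken, c(s, e))
  }
  nrow(taken)
}

#' Self dot plot of exact word matches (both strands)
#'
#' @param seq DNA string
#' @param word word length
#' @return data.frame with 1-based `x`, `y` word start coordinates and
#'   `strand` ("+" for direct matches including the main diagonal, "-" for
#'   reverse-complement matches; y is the forward-strand start of the matched
#'   word)
#' @export
dotplot <- function(seq, word = 15) {
  n <- nchar(seq)
  pos <- seq_len(n - word + 1L)
  fw <- substring(seq, pos, pos + word - 1L)
  match_pairs <- function(wa, wb) {
    o <- order(c(wa, wb), method = "radix")
    lab <- c(rep(1L, length(wa)), rep(2L, length(wb)))[o]
    idx <- c(seq_along(wa), seq_along(wb))[o]
    w <- c(wa, wb)[o]
    r <- rle(w)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    res <- list()
    for (g in which(r$lengths > 1)) {
      ii <- starts[g]:ends[g]
      a <- idx[ii][lab[ii] == 1L]; b <- idx[ii][lab[ii] == 2L]
      if (length(a) && length(b))
        res[[length(res) + 1L]] <- expand.grid(x = a, y = b)
    }
    if (length(res)) do.call(rbind, res) else
      data.frame(x = integer(0), y = integer(0))
  }
  # direct matches (self): all pairs within identical-word groups
  o <- order(fw, method = "radix")
  w <- fw[o]
  r <- rle(w)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  fwd <- list()
  for (g in seq_along(r$lengths)) {
    p <- pos[o[starts[g]:ends[g]]]
    fwd[[g]] <- expand.grid(x = p, y = p)
  }
  fwd <- do.call(rbind, fwd)
  fwd$strand <- "+"
  # reverse-complement matches
  rcseq <- revcomp(seq)
  rw <- substring(rcseq, pos, pos + word - 1L)
  rc <- match_pairs(fw, rw)
  if (nrow(rc)) {
    rc$y <- n - (rc$y + word - 1L) + 1L # forward start of the rc word
    rc$strand <- "-"
  } else rc$strand <- character(0)
  out <- rbind(fwd, rc)
  rownames(out) <- NULL
  out
}

#' Mask a genome with a consensus library under a divergence cap and report
#' coverage
#'
#' Seed-and-extend (exact 15-mers grouped by diagonal, banded local
#' alignment) local matches of each library sequence, both strands;
#' alignments whose divergence (1 - matches/alignment-length) is at most
#' `max_divergence` contribute intervals. Intervals are merged; coverage is
#' reported over total assembly length and excluding N-gap runs.
#'
#' @param genome named character vector of contigs (or `sim_genome`)
#' @param consensus_library named character vector of library sequences
#' @param max_divergence accepted divergence between target and query
#' @param k seed word size
#' @param band band half-width for the local alignment
#' @return list of class `masked_annotation`: `intervals` (contig, start, end;
#'   0-based half-open), `masked_bp`, `assembly_bp`, `gap_bp`, `coverage`,
#'   `coverage_excl_gaps`
#' @export
mask_coverage <- function(genome, consensus_library, max_divergence = 0.20,
                          k = 15, band = 400) {
  if (inherits(genome, "sim_genome")) genome <- genome$fasta
  iv <- list()
  for (contig in names(genome)) {
    g <- genome[[contig]]
    n <- nchar(g)
    gpos <- seq_len(max(0L, n - k + 1L))
    gwords <- substring(g, gpos, gpos + k - 1L)
    g_int <- dna_to_int(g)
    for (lib_id in names(consensus_library)) {
      for (strand in c("+", "-")) {
        q <- consensus_library[[lib_id]]
        if (strand == "-") q <- revcomp(q)
        m <- nchar(q)
        if (m < k) next
        qpos <- seq_len(m - k + 1L)
        qwords <- substring(q, qpos, qpos + k - 1L)
        hit <- match(gwords, qwords)
        ii <- which(!is.na(hit))
        if (!length(ii)) next
        jj <- qpos[hit[ii]]
        diag <- ii - jj
        o <- order(diag, ii)
        ii <- ii[o]; jj <- jj[o]; diag <- diag[o]
        grp <- cumsum(c(1, diff(diag) > band | diff(ii) > 2000))
        q_int <- dna_to_int(q)
        for (gid in unique(grp)) {
          sel <- grp == gid
          if (sum(sel) < 2) next
          gi <- ii[sel]; qi <- jj[sel]
          g_lo <- max(1L, min(gi) - min(qi))
          g_hi <- min(n, max(gi) + k - 1L + (m - max(qi)))
          sub <- g_int[g_lo:g_hi]
          d0 <- as.integer(median(gi - qi)) - (g_lo - 1L)
          al <- banded_local_cpp(q_int, sub, diag = d0, band = band,
                                 match = 1, mismatch = -1,
                                 gap_open = -5, gap_ext = -1)
          if (al$aln_len < k) next
          div <- 1 - al$matches / al$aln_len
          if (div <= max_divergence) {
            iv[[length(iv) + 1L]] <- data.frame(
              contig = contig, start = g_lo - 1L + al$b_start - 1L,
              end = g_lo - 1L + al$b_end, stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  assembly_bp <- sum(nchar(genome))
  gap_bp <- sum(vapply(genome, function(s)
    sum(split1(s) == "N"), numeric(1)))
  if (!length(iv)) {
    return(structure(list(
      intervals = data.frame(contig = character(0), start = integer(0),
                             end = integer(0)),
      masked_bp = 0L, assembly_bp = assembly_bp, gap_bp = gap_bp,
      coverage = 0, coverage_excl_gaps = 0), class = "masked_annotation"))
  }
  iv <- do.call(rbind, iv)
  merged <- lapply(split(iv, iv$contig), function(d) {
    red <- IRanges::reduce(IRanges::IRanges(d$start + 1L, d$end))
    data.frame(contig = d$contig[1], start = IRanges::start(red) - 1L,
               end = IRanges::end(red), stringsAsFactors = FALSE)
  })
  merged <- do.call(rbind, merged)
  rownames(merged) <- NULL
  masked <- sum(merged$end - merged$start)
  structure(list(intervals = merged, masked_bp = masked,
                 assembly_bp = assembly_bp, gap_bp = gap_bp,
                 coverage = masked / assembly_bp,
                 coverage_excl_gaps = masked / (assembly_bp - gap_bp)),
            class = "masked_annotation")
}
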