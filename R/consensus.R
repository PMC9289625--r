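#' k-mer count profiles for a set of sequences
#' @keywords internal
kmer_counts <- function(seqs, k = 8, alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "dna") {
    return(Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(gsub("[^ACGT]", "A", seqs)), width = k))
  }
  # amino acids: dimer counts are plenty for a guide tree
  k <- min(k, 2)
  dimers <- as.vector(outer(AA20, AA20, paste0))
  t(vapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 2) return(setNames(numeric(length(dimers)), dimers))
    tab <- table(factor(substring(s, 1:(n - 1), 2:n), levels = dimers))
    as.numeric(tab)
  }, numeric(length(dimers))))
}

cosine_sim <- function(x, y) {
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) return(0)
  sum(x * y) / (nx * ny)
}

# integer coding for alignment columns: residues 1..S-1, gap/other -> S
msa_codes <- function(x, alphabet = "dna") {
  letters <- if (alphabet == "dna") DNA_BASES4 else AA20
  S <- length(letters) + 1L
  code <- rep(S, 128)
  for (i in seq_along(letters)) code[utf8ToInt(letters[i]) + 1L] <- i
  code[utf8ToInt(x) + 1L]
}

char_matrix_profile <- function(m, alphabet = "dna") {
  # m: character matrix rows = sequences; returns S x ncol count matrix
  S <- if (alphabet == "dna") 5L else 21L
  L <- ncol(m)
  counts <- matrix(0, S, L)
  for (r in seq_len(nrow(m))) {
    v <- msa_codes(paste(m[r, ], collapse = ""), alphabet)
    for (s in seq_len(S)) counts[s, ] <- counts[s, ] + (v == s)
  }
  counts
}

#' Greedy coverage-based clustering of extended loci
#'
#' A locus joins the first representative whose banded local alignment covers
#' at least `min_cov` of the shorter sequence at `min_identity` or better;
#' otherwise it founds a new cluster. Loci longer than `max_seq_len` are
#' excluded up front. Clusters with fewer than `min_members` members are
#' reported but flagged ineligible for consensus building. An 8-mer cosine
#' pre-filter skips alignments between sequences with essentially no shared
#' k-mer content.
#'
#' @param loci `extended_loci` data.frame from [extend_loci()]
#' @param min_cov minimum aligned coverage of the shorter sequence
#' @param min_identity minimum local alignment identity
#' @param min_members members needed for consensus eligibility
#' @param max_seq_len hard cap on locus length admitted to clustering
#' @param band extra band width for the banded local alignment
#' @param prefilter_sim cosine similarity below which alignment is skipped
#' @return list of class `locus_clusters`; each element has `representative`,
#'   `members` and `eligible`
#' @export
cluster_loci <- function(loci, min_cov = 0.5, min_identity = 0.8,
                         min_members = 5, max_seq_len = 15000,
                         band = 800, prefilter_sim = 0.12) {
  loci <- loci[nchar(loci$seq) <= max_seq_len, , drop = FALSE]
  if (!nrow(loci)) return(structure(list(), class = "locus_clusters"))
  ord <- order(-nchar(loci$seq), loci$locus_id)
  loci <- loci[ord, , drop = FALSE]
  km <- kmer_counts(loci$seq)
  rownames(km) <- loci$locus_id
  seq_int <- lapply(loci$seq, dna_to_int)
  names(seq_int) <- loci$locus_id
  reps <- character(0)
  members <- list()
  for (i in seq_len(nrow(loci))) {
    id <- loci$locus_id[i]
    joined <- FALSE
    for (r in seq_along(reps)) {
      if (cosine_sim(km[id, ], km[reps[r], ]) < prefilter_sim) next
      a <- seq_int[[id]]; b <- seq_int[[reps[r]]]
      w <- abs(length(a) - length(b)) + band
      al <- banded_local_cpp(a, b, diag = 0L, band = w,
                             match = 1, mismatch = -1,
                             gap_open = -5, gap_ext = -1)
      if (al$aln_len == 0) next
      shorter <- min(length(a), length(b))
      span <- if (length(a) <= length(b)) al$a_end - al$a_start + 1L else
        al$b_end - al$b_start + 1L
      cov <- span / shorter
      ident <- al$matches / al$aln_len
      if (cov >= min_cov && ident >= min_identity) {
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
         eligible = length(members[[r]]) >= min_members)
  })
  structure(out, class = "locus_clusters")
}

#' Progressive multiple alignment of a cluster of nucleotide sequences
#'
#' Guide tree from 8-mer cosine distances (average-linkage clustering);
#' profile-profile Needleman-Wunsch with affine gaps at each merge, banded
#' around the main diagonal. Deterministic.
#'
#' @param seqs named character vector (2-50 sequences; a single sequence
#'   yields a trivial one-row alignment)
#' @param band band half-width for the profile alignment
#' @param match,mismatch,gap_open,gap_ext alignment scores
#' @param alphabet "dna" (default) or "aa"
#' @return object of class `msa`: list with `matrix` (character matrix, rows
#'   named by sequence id) and `ids`
#' @export
align_cluster <- function(seqs, band = 512, match = 1, mismatch = -1,
                          gap_open = -5, gap_ext = -1,
                          alphabet = c("dna", "aa")) {
  alphabet <- match.arg(alphabet)
  n <- length(seqs)
  if (n == 0) stop("no sequences to align")
  ids <- names(seqs)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  if (n == 1) {
    m <- matrix(split1(seqs[[1]]), nrow = 1, dimnames = list(ids, NULL))
    return(structure(list(matrix = m, ids = ids), class = "msa"))
  }
  if (n > 50) stop("align_cluster accepts at most 50 sequences")
  km <- kmer_counts(seqs, alphabet = alphabet)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- 1 - cosine_sim(km[i, ], km[j, ])
  }
  tr <- hclust(as.dist(d), method = "average")

  alns <- lapply(seq_len(n), function(i)
    matrix(split1(seqs[[i]]), nrow = 1, dimnames = list(ids[i], NULL)))
  merged <- vector("list", nrow(tr$merge))
  get_aln <- function(idx) if (idx < 0) alns[[-idx]] else merged[[idx]]
  for (s in seq_len(nrow(tr$merge))) {
    A <- get_aln(tr$merge[s, 1])
    B <- get_aln(tr$merge[s, 2])
    pa <- profile_align_cpp(char_matrix_profile(A, alphabet),
                            char_matrix_profile(B, alphabet),
                            match, mismatch, gap_open, gap_ext, band)
    L <- length(pa$path_a)
    out <- matrix("-", nrow(A) + nrow(B), L)
    rownames(out) <- c(rownames(A), rownames(B))
    ka <- pa$path_a > 0
    out[seq_len(nrow(A)), which(ka)] <- A[, pa$path_a[ka], drop = FALSE]
    kb <- pa$path_b > 0
    out[nrow(A) + seq_len(nrow(B)), which(kb)] <- B[, pa$path_b[kb],
                                                    drop = FALSE]
    merged[[s]] <- out
  }
  m <- merged[[nrow(tr$merge)]]
  m <- m[ids, , drop = FALSE]
  structure(list(matrix = m, ids = ids), class = "msa")
}

#' Recover the ungapped sequence of one alignment row
#' @param msa an `msa` object
#' @param id row id
#' @export
ungap_row <- function(msa, id) {
  paste(msa$matrix[id, msa$matrix[id, ] != "-"], collapse = "")
}

#' Call a consensus from a multiple alignment with the match-ratio rule
#'
#' A column is a match column iff its non-gap fraction is at least
#' `match_ratio` (boundary inclusive). The consensus emits, for each match
#' column, the most frequent non-gap residue (ties broken alphabetically);
#' non-match columns are dropped.
#'
#' @param msa an `msa` object (or bare character matrix)
#' @param match_ratio minimum non-gap fraction for a match column
#' @param species_id species label carried on the record
#' @param consensus_id identifier for the record
#' @return list of class `consensus_record`: `seq`, `species_id`,
#'   `consensus_id`, `member_count`, `member_ids`, `match_cols`
#' @export
consensus_from_msa <- function(msa, match_ratio = 0.5, species_id = NA,
                               consensus_id = NA) {
  m <- if (inherits(msa, "msa")) msa$matrix else msa
  n <- nrow(m)
  nongap <- colSums(m != "-")
  match_cols <- which(nongap / n >= match_ratio)
  bases <- vapply(match_cols, function(j) {
    col <- m[, j]
    col <- col[col != "-"]
    tab <- table(col)
    names(tab)[which.max(tab)] # ties: first alphabetically (table is sorted)
  }, character(1))
  structure(list(seq = paste(bases, collapse = ""), species_id = species_id,
                 consensus_id = consensus_id, member_count = n,
                 member_ids = rownames(m), match_cols = match_cols),
            class = "consensus_record")
}
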