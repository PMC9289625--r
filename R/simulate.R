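#' Specify a synthetic LTR-retrotransposon family
#'
#' Describes the master (ancestral) element of one family: overall size, LTR
#' length, the ORF cassette plan, PBS/PPT presence, terminal inverted repeat
#' length, the per-copy substitution rate and the copy number with which the
#' family is implanted into a genome.
#'
#' @param family_id family label
#' @param total_len total element length (nt), LTR to LTR inclusive
#' @param ltr_len LTR length (nt); the two LTRs are identical on the master
#' @param orf_specs list of ORF descriptions, each a list with `orf_id`,
#'   `aa_length` (codON count including the initial Met, excluding the stop)
#'   and `cassettes` (character vector of profile labels to embed, in order)
#' @param pbs_trna tRNA label the primer binding site is antisense to, or NA
#' @param ppt logical; implant a polypurine tract just 5' of the 3' LTR
#' @param tir_len terminal inverted repeat length at the LTR extremities (0-10)
#' @param divergence expected per-copy substitution fraction, in [0, 0.3)
#' @param copy_number number of copies implanted per genome
#' @param pbs_len PBS length in nt (12-18)
#' @param indels logical; allow a few short indels in internal padding per copy
#' @return object of class `element_spec`
#' @export
element_spec <- function(family_id, total_len, ltr_len, orf_specs,
                         pbs_trna = "tRNA-Arg", ppt = TRUE, tir_len = 5,
                         divergence = 0.02, copy_number = 1,
                         pbs_len = 14, indels = FALSE) {
  stopifnot(total_len > 0, ltr_len > 0, 2 * ltr_len < total_len)
  if (divergence < 0 || divergence >= 0.3)
    stop("divergence must lie in [0, 0.3)")
  if (tir_len < 0 || tir_len > 10) stop("tir_len must lie in [0, 10]")
  if (pbs_len < 12 || pbs_len > 18) stop("pbs_len must lie in [12, 18]")
  structure(list(family_id = family_id, total_len = as.integer(total_len),
                 ltr_len = as.integer(ltr_len), orf_specs = orf_specs,
                 pbs_trna = pbs_trna, ppt = ppt, tir_len = as.integer(tir_len),
                 divergence = divergence, copy_number = as.integer(copy_number),
                 pbs_len = as.integer(pbs_len), indels = indels),
            class = "element_spec")
}

orf_nt_len <- function(orf) as.integer(orf$aa_length) * 3L + 3L

#' Generate the master sequence of an element family
#'
#' Lays the element out as `LTR5 - PBS - padding/ORFs/padding - PPT - LTR3`.
#' The two LTRs are identical and begin/end with a short terminal inverted
#' repeat (canonical TG...CA when `tir_len >= 2`). The PBS is the reverse
#' complement of the 3'-terminal `pbs_len` nt of the named tRNA, placed
#' immediately 3' of the 5' LTR; the PPT is a purine run immediately 5' of the
#' 3' LTR. ORFs are stop-free codon runs on the plus strand, each embedding
#' its requested domain cassettes (the profile master sequence with light
#' amino-acid noise).
#'
#' @param spec an [element_spec()]
#' @param seed integer seed
#' @param library profile library from [generate_profile_library()]; required
#'   when cassettes are requested or a PBS tRNA is named
#' @param cassette_noise per-residue substitution rate applied to embedded
#'   cassette amino-acid sequences
#' @param gc background GC fraction for LTRs and padding
#' @return list with `seq` (nt string), `features` (data.frame feature, label,
#'   start, end; 0-based half-open element coordinates) and `orf_aa` (named
#'   character vector of ORF translations)
#' @export
generate_element <- function(spec, seed = 1, library = NULL,
                             cassette_noise = 0.02, gc = 0.4) {
  stopifnot(inherits(spec, "element_spec"))
  with_seed(seed, {
    pbs_nt <- if (!is.na(spec$pbs_trna)) spec$pbs_len else 0L
    ppt_nt <- if (isTRUE(spec$ppt)) 12L else 0L
    orf_nt <- vapply(spec$orf_specs, orf_nt_len, integer(1))
    n_gaps <- length(spec$orf_specs) + 1L
    pad_total <- spec$total_len - 2L * spec$ltr_len - pbs_nt - ppt_nt -
      sum(orf_nt)
    if (pad_total < 0)
      stop("element sizing error: features exceed total_len by ",
           -pad_total, " nt")
    pads <- rep(pad_total %/% n_gaps, n_gaps)
    pads[n_gaps] <- pads[n_gaps] + pad_total %% n_gaps

    # LTR with terminal inverted repeat
    ltr <- split1(random_dna(spec$ltr_len, gc))
    if (spec$tir_len >= 2) {
      tir <- c("T", "G", sample(DNA_BASES4, spec$tir_len - 2, replace = TRUE))
      ltr[seq_len(spec$tir_len)] <- tir
      ltr[(spec$ltr_len - spec$tir_len + 1):spec$ltr_len] <-
        split1(revcomp(paste(tir, collapse = "")))
    }
    ltr <- paste(ltr, collapse = "")

    feats <- list()
    orf_aa <- character(0)
    pos <- 0L
    add_feat <- function(feature, label, len) {
      feats[[length(feats) + 1L]] <<- data.frame(
        feature = feature, label = label, start = pos, end = pos + len,
        stringsAsFactors = FALSE)
      pos <<- pos + as.integer(len)
    }

    parts <- character(0)
    push <- function(s) parts[[length(parts) + 1L]] <<- s

    push(ltr); add_feat("long_terminal_repeat", "LTR5", spec$ltr_len)
    if (pbs_nt > 0) {
      trna <- library$trna[[spec$pbs_trna]]
      if (is.null(trna)) stop("tRNA '", spec$pbs_trna, "' not in library")
      pbs <- revcomp(substr(trna, nchar(trna) - pbs_nt + 1L, nchar(trna)))
      push(pbs); add_feat("primer_binding_site", spec$pbs_trna, pbs_nt)
    }
    for (i in seq_along(spec$orf_specs)) {
      # terminate the pad with an in-frame stop so the designed ATG->stop
      # span is maximal (no silent upstream extension through the padding)
      pad <- random_dna(pads[i], gc)
      if (pads[i] >= 3)
        pad <- paste0(substr(pad, 1, pads[i] - 3),
                      sample(c("TAA", "TGA", "TAG"), 1))
      push(pad); pos <- pos + pads[i]
      orf <- spec$orf_specs[[i]]
      aa <- design_orf_aa(orf, library, cassette_noise)
      orf_start <- pos
      push(paste0(aa$dna, sample(c("TAA", "TGA", "TAG"), 1)))
      add_feat("ORF", orf$orf_id, orf$aa_length * 3L + 3L)
      for (k in seq_len(nrow(aa$cassettes))) {
        cz <- aa$cassettes[k, ]
        feats[[length(feats) + 1L]] <- data.frame(
          feature = "domain", label = cz$label,
          start = orf_start + (cz$aa_start - 1L) * 3L,
          end = orf_start + cz$aa_end * 3L, stringsAsFactors = FALSE)
      }
      orf_aa[orf$orf_id] <- aa$aa
    }
    push(random_dna(pads[n_gaps], gc)); pos <- pos + pads[n_gaps]
    if (ppt_nt > 0) {
      ppt <- paste(sample(c("A", "G"), ppt_nt, replace = TRUE,
                          prob = c(0.5, 0.5)), collapse = "")
      push(ppt); add_feat("RR_tract", "PPT", ppt_nt)
    }
    push(ltr); add_feat("long_terminal_repeat", "LTR3", spec$ltr_len)

    seq <- paste(unlist(parts), collapse = "")
    stopifnot(nchar(seq) == spec$total_len)
    features <- do.call(rbind, feats)
    features <- features[order(features$start), , drop = FALSE]
    rownames(features) <- NULL
    list(seq = seq, features = features, orf_aa = orf_aa)
  })
}

# design one ORF's amino-acid sequence with embedded cassettes
design_orf_aa <- function(orf, library, cassette_noise) {
  aa_len <- orf$aa_length
  cassettes <- orf$cassettes
  if (is.null(cassettes)) cassettes <- character(0)
  cass_aa <- lapply(cassettes, function(lab) {
    pr <- library$profiles[[lab]]
    if (is.null(pr)) stop("profile '", lab, "' not in library")
    mutate_aa(pr$master, cassette_noise)
  })
  cass_len <- vapply(cass_aa, nchar, integer(1))
  filler_total <- aa_len - 1L - sum(cass_len)
  if (filler_total < 0)
    stop("element sizing error: cassettes exceed ORF length")
  k <- length(cassettes)
  fills <- rep(filler_total %/% (k + 1L), k + 1L)
  fills[k + 1L] <- fills[k + 1L] + filler_total %% (k + 1L)
  aa <- "M"
  rows <- list()
  for (i in seq_len(k)) {
    aa <- paste0(aa, random_aa(fills[i]))
    st <- nchar(aa) + 1L
    aa <- paste0(aa, cass_aa[[i]])
    rows[[i]] <- data.frame(label = cassettes[i], aa_start = st,
                            aa_end = nchar(aa), stringsAsFactors = FALSE)
  }
  aa <- paste0(aa, random_aa(fills[k + 1L]))
  stopifnot(nchar(aa) == aa_len)
  cass_df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(label = character(0), aa_start = integer(0),
               aa_end = integer(0))
  list(aa = aa, dna = encode_orf_aa(aa), cassettes = cass_df)
}

#' Derive a diverged subfamily master from an existing element master
#'
#' Models lineage diversification: the subfamily master is the parent master
#' with iid substitutions at `rate`, keeping the feature map (coordinates are
#' preserved because divergence is substitution-only). Copies generated from
#' different subfamily masters then cluster separately, each yielding its own
#' consensus — the situation in which a domain carried by the whole lineage
#' is seen in many consensus sequences of one species.
#'
#' The two LTRs stay identical on the derived master: replication copies
#' both LTRs from one template, so LTR-pair identity resets at every
#' insertion regardless of how far the lineage has diverged.
#'
#' @param master element master list from [generate_element()]
#' @param rate per-site substitution rate from the parent master
#' @param seed integer seed
#' @return element master list (seq, features; orf_aa dropped as stale)
#' @export
derive_subfamily <- function(master, rate, seed) {
  with_seed(seed, {
    seq <- mutate_dna(master$seq, rate)
    ltrs <- master$features[master$features$feature == "long_terminal_repeat", ]
    if (nrow(ltrs) == 2) {
      l5 <- substr(seq, ltrs$start[1] + 1, ltrs$end[1])
      substr(seq, ltrs$start[2] + 1, ltrs$end[2]) <- l5
    }
    list(seq = seq, features = master$features)
  })
}

#' Specify a synthetic genome
#'
#' @param species_id species label
#' @param genome_len contig length (nt); the genome is a single contig
#' @param elements list of [element_spec()] objects; each may carry a
#'   pre-built `master` (as returned by [generate_element()]) to model
#'   subfamily lineages that share ancestry
#' @param gc background GC fraction
#' @param gap_runs list of c(position, length) N-runs (0-based positions)
#' @param seed integer seed
#' @param min_spacing minimum distance between implanted copies (nt)
#' @return object of class `genome_spec`
#' @export
genome_spec <- function(species_id, genome_len, elements = list(), gc = 0.4,
                        gap_runs = list(), seed = 1, min_spacing = 0) {
  structure(list(species_id = species_id, genome_len = as.integer(genome_len),
                 elements = elements, gc = gc, gap_runs = gap_runs,
                 seed = as.integer(seed), min_spacing = as.integer(min_spacing)),
            class = "genome_spec")
}

#' Generate a synthetic genome with ground-truth annotations
#'
#' The background is iid with the requested GC. Family master sequences are
#' implanted `copy_number` times each; per-copy divergence is realized as iid
#' substitutions (indels only when opted in). Copies land on either strand at
#' non-overlapping positions; N-gap runs are written last. Deterministic given
#' the spec (seed included).
#'
#' @param spec a [genome_spec()]
#' @param library profile library (passed to [generate_element()] for families
#'   without a pre-built master)
#' @return list of class `sim_genome` with `fasta` (named character vector,
#'   one contig), `truth` (list: `copies` and `features` data.frames, 0-based
#'   half-open genome coordinates) and `spec`
#' @export
generate_genome <- function(spec, library = NULL) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    genome <- split1(random_dna(spec$genome_len, spec$gc))
    copies <- list(); feats <- list()
    # randomized slot placement: one slot per copy guarantees non-overlap
    # and the requested spacing whenever the slots are wide enough
    n_copies <- sum(vapply(spec$elements, function(e)
      as.integer(e$copy_number), integer(1)))
    slot_order <- if (n_copies) sample.int(n_copies) else integer(0)
    slot_size <- if (n_copies) spec$genome_len %/% n_copies else 0L
    placed <- matrix(numeric(0), ncol = 2)
    copy_n <- 0L
    for (el in spec$elements) {
      master <- el$master
      if (is.null(master))
        master <- generate_element(el, seed = sample.int(2^31 - 1L, 1),
                                   library = library, gc = spec$gc)
      mlen <- nchar(master$seq)
      for (cp in seq_len(el$copy_number)) {
        copy_n <- copy_n + 1L
        cid <- paste0(el$family_id, "_c", cp)
        mut <- mutate_dna(master$seq, el$divergence)
        mf <- master$features
        if (isTRUE(el$indels)) {
          res <- apply_padding_indels(mut, mf, el$ltr_len)
          mut <- res$seq; mf <- res$features
        }
        clen <- nchar(mut)
        strand <- if (runif(1) < 0.5) "+" else "-"
        slot <- slot_order[copy_n]
        slack <- slot_size - clen - spec$min_spacing
        if (slack < 0)
          stop("placement error: copy ", cid, " does not fit its slot; ",
               "enlarge the genome or reduce spacing")
        start <- (slot - 1L) * slot_size + spec$min_spacing %/% 2L +
          sample.int(max(1L, slack), 1) - 1L
        start <- min(start, spec$genome_len - clen)
        placed <- rbind(placed, c(start, start + clen))
        inserted <- if (strand == "+") mut else revcomp(mut)
        genome[(start + 1):(start + clen)] <- split1(inserted)
        ident <- if (isTRUE(el$indels)) NA_real_ else
          hamming_identity(master$seq, mut)
        copies[[copy_n]] <- data.frame(
          copy_id = cid, species_id = spec$species_id,
          family_id = el$family_id, contig = "chr1",
          start = start, end = start + clen, strand = strand,
          identity = if (isTRUE(el$indels)) NA_real_ else ident,
          stringsAsFactors = FALSE)
        gf <- mf
        if (strand == "+") {
          gf$start <- start + gf$start; gf$end <- start + gf$end
        } else {
          s2 <- start + clen - mf$end; e2 <- start + clen - mf$start
          gf$start <- s2; gf$end <- e2
        }
        gf$copy_id <- cid; gf$strand <- strand
        feats[[copy_n]] <- gf
      }
    }
    for (g in spec$gap_runs) {
      i0 <- g[1]; len <- g[2]
      if (i0 + len > spec$genome_len) stop("gap run exceeds genome")
      if (nrow(placed) && any(pmax(placed[, 1], i0) < pmin(placed[, 2], i0 + len)))
        stop("gap run overlaps an implanted element")
      genome[(i0 + 1):(i0 + len)] <- "N"
    }
    fasta <- setNames(paste(genome, collapse = ""), "chr1")
    truth <- list(
      copies = if (copy_n) do.call(rbind, copies) else
        data.frame(copy_id = character(0)),
      features = if (copy_n) do.call(rbind, feats) else
        data.frame(copy_id = character(0)))
    structure(list(fasta = fasta, truth = truth, spec = spec),
              class = "sim_genome")
  })
}

# a few short indels confined to internal padding (between annotated features)
apply_padding_indels <- function(seq, features, ltr_len, n_indels = 2,
                                 max_len = 5) {
  len <- nchar(seq)
  padding_positions <- function(len, features) {
    setdiff(seq.int(ltr_len + 1L, len - ltr_len),
            unlist(mapply(function(s, e) seq.int(s + 1L, e),
                          features$start, features$end, SIMPLIFY = FALSE)))
  }
  internal <- padding_positions(len, features)
  if (!length(internal)) return(list(seq = seq, features = features))
  for (i in seq_len(n_indels)) {
    p <- sample(internal, 1)
    d <- sample.int(max_len, 1)
    if (runif(1) < 0.5) { # deletion at p of length d
      d <- min(d, max(internal) - p + 1L)
      seq <- paste0(substr(seq, 1, p - 1L), substr(seq, p + d, nchar(seq)))
      sh <- features$start >= p; features$start[sh] <- features$start[sh] - d
      sh <- features$end >= p; features$end[sh] <- features$end[sh] - d
    } else { # insertion at p
      seq <- paste0(substr(seq, 1, p - 1L), random_dna(d),
                    substr(seq, p, nchar(seq)))
      sh <- features$start >= p; features$start[sh] <- features$start[sh] + d
      sh <- features$end >= p; features$end[sh] <- features$end[sh] + d
    }
    len <- nchar(seq)
    internal <- padding_positions(len, features)
    if (!length(internal)) break
  }
  list(seq = seq, features = features)
}

#' Generate a synthetic EMSA binding series
#'
#' Fraction bound follows the Hill isotherm theta(P) = P^n / (Kd^n + P^n);
#' Gaussian noise is added and the result truncated to (0, 1). The recorded
#' observable is the free-RNA signal, `total * (1 - theta)`, plus a
#' zero-protein lane carrying the total signal.
#'
#' @param kd dissociation constant (uM), > 0
#' @param hill_n Hill coefficient
#' @param concentrations protein concentrations (uM), all > 0
#' @param noise_sd Gaussian noise sd on theta (fraction)
#' @param seed integer seed (only used when noise_sd > 0)
#' @param total total signal in the zero-protein lane (arbitrary units)
#' @return data.frame of class `binding_series` with columns `conc` and
#'   `free`; the first row is the zero-protein lane
#' @export
generate_binding_series <- function(kd, hill_n = 1, concentrations,
                                    noise_sd = 0, seed = 1, total = 1000) {
  if (kd <= 0) stop("kd must be positive")
  if (any(concentrations <= 0)) stop("concentrations must be positive")
  theta <- concentrations^hill_n / (kd^hill_n + concentrations^hill_n)
  if (noise_sd > 0) {
    theta <- with_seed(seed, theta + rnorm(length(theta), 0, noise_sd))
    theta <- pmin(pmax(theta, 1e-6), 1 - 1e-6)
  }
  out <- data.frame(conc = c(0, concentrations),
                    free = c(total, total * (1 - theta)))
  attr(out, "total") <- total
  class(out) <- c("binding_series", "data.frame")
  out
}

#' Generate synthetic UPLC chromatograms realizing requested m6A/A ratios
#'
#' Each chromatogram is a regular trace of Gaussian peaks for guanosine (G),
#' adenosine (A) and N6-methyladenosine (m6A) at fixed retention-time centers;
#' the m6A peak area is `ratio * area_A`.
#'
#' @param species_ratios named numeric vector, label -> m6A/A area ratio (>= 0)
#' @param peak_params list overriding any of: centers (named numeric, min),
#'   sd (peak width, min), area_A, area_G, dt, t_max, baseline, noise_sd
#' @param seed integer seed (used when noise_sd > 0)
#' @return named list of `chromatogram` objects, each with `trace`
#'   (data.frame rt, intensity) and `label`
#' @export
generate_chromatogram <- function(species_ratios, peak_params = list(),
                                  seed = 1) {
  if (any(species_ratios < 0)) stop("ratios must be >= 0")
  p <- modifyList(list(centers = c(G = 2, A = 4, m6A = 6), sd = 0.05,
                       area_A = 10, area_G = 20, dt = 0.005, t_max = 8,
                       baseline = 0.5, noise_sd = 0), peak_params)
  t <- seq(0, p$t_max, by = p$dt)
  with_seed(seed, {
    out <- lapply(names(species_ratios), function(lab) {
      areas <- c(G = p$area_G, A = p$area_A,
                 m6A = unname(species_ratios[[lab]]) * p$area_A)
      y <- rep(p$baseline, length(t))
      for (pk in names(p$centers))
        y <- y + areas[[pk]] * dnorm(t, p$centers[[pk]], p$sd)
      if (p$noise_sd > 0) y <- pmax(y + rnorm(length(t), 0, p$noise_sd), 0)
      structure(list(trace = data.frame(rt = t, intensity = y), label = lab),
                class = "chromatogram")
    })
    setNames(out, names(species_ratios))
  })
}
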