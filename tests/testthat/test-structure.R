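# contig with one implanted direct-repeat pair (identical LTRs unless
# diverged), returning truth boundaries
ltr_contig <- function(ltr_len = 1000, offset = 12000, flank = 3000,
                       div = 0, seed = 80) {
  with_seed(seed, {
    ltr <- paste0("TG", random_dna(ltr_len - 4), "CA")
    internal <- random_dna(offset - ltr_len)
    ltr2 <- mutate_dna(ltr, div)
    seq <- paste0(random_dna(flank), ltr, internal, ltr2,
                  random_dna(flank))
    list(seq = seq, ltr5_start = flank, ltr5_end = flank + ltr_len,
         ltr3_start = flank + offset, ltr3_end = flank + offset + ltr_len)
  })
}

test_that("an implanted identical LTR pair is recovered exactly", {
  tc <- ltr_contig()
  lp <- find_ltr_pairs(tc$seq)
  expect_equal(nrow(lp), 1)
  expect_equal(lp$ltr_len, 1000)
  expect_equal(lp$ltr_identity, 1.0)
  expect_equal(lp$ltr5_start, tc$ltr5_start)
  expect_equal(lp$ltr3_end, tc$ltr3_end)
})

test_that("over-length LTRs are rejected at the cap and found when raised", {
  el <- fixture_reference_element()
  set.seed(81)
  contig <- paste0(random_dna(4000), el$seq, random_dna(4000))
  at3000 <- find_ltr_pairs(contig, max_ltr_len = 3000)
  expect_equal(nrow(at3000), 0)
  at7000 <- find_ltr_pairs(contig, max_ltr_len = 7000)
  expect_equal(nrow(at7000), 1)
  expect_equal(at7000$ltr_len, 6425)
  expect_equal(at7000$end - at7000$start, 25510)
})

test_that("boundaries stay within 5 nt of truth at 5% divergence", {
  for (s in 1:12) {
    tc <- ltr_contig(ltr_len = 800, offset = 9000, div = 0.05,
                     seed = 500 + s)
    lp <- find_ltr_pairs(tc$seq, min_ltr_identity = 0.85)
    expect_equal(nrow(lp), 1, info = paste("seed", s))
    expect_lte(abs(lp$ltr5_start - tc$ltr5_start), 5)
    expect_lte(abs(lp$ltr3_end - tc$ltr3_end), 5)
  }
})

test_that("LTR detection is strand-symmetric", {
  tc <- ltr_contig(seed = 82)
  n <- nchar(tc$seq)
  fwd <- find_ltr_pairs(tc$seq)
  rev <- find_ltr_pairs(revcomp(tc$seq))
  expect_equal(nrow(rev), 1)
  expect_equal(rev$start, n - fwd$end)
  expect_equal(rev$end, n - fwd$start)
})

test_that("element-free contigs yield no LTR pairs", {
  for (s in 1:5) {
    seq <- with_seed(600 + s, random_dna(30000))
    expect_equal(nrow(find_ltr_pairs(seq)), 0)
  }
})

test_that("TIR detection equals brute force over prefix lengths", {
  with_seed(83, {
    core <- random_dna(200)
    tir <- "TGTAT"
    ltr <- paste0(tir, core, revcomp(tir))
    expect_gte(detect_tir(ltr), 3)
    # brute-force oracle
    brute <- 0L
    n <- nchar(ltr)
    for (L in 12:3) {
      if (revcomp(substr(ltr, 1, L)) == substr(ltr, n - L + 1, n)) {
        brute <- L
        break
      }
    }
    expect_equal(detect_tir(ltr), brute)
    # random LTR with no inverted termini
    ltr2 <- paste0("AAAA", core, "AAAA")
    expect_equal(detect_tir(ltr2), 0L)
  })
})

test_that("ORF caller reports designed lengths and matches a frame-scan oracle", {
  el <- fixture_reference_element()
  internal <- substr(el$seq, 6426, 19085)
  orfs <- find_orfs(internal, min_aa = 300)
  plus <- orfs[orfs$strand == "+", ]
  expect_equal(plus$aa_len[1:2], c(2640, 565))
  # all-stop sequence
  expect_equal(nrow(find_orfs(strrep("TAA", 100), min_aa = 1)), 0)
  # oracle: independent per-frame scan on a small random sequence
  set.seed(84)
  s <- random_dna(600)
  got <- find_orfs(s, min_aa = 5)
  oracle <- list()
  for (strand in c("+", "-")) {
    ss <- if (strand == "+") s else revcomp(s)
    for (f in 1:3) {
      m <- nchar(ss) - f + 1; m <- m - m %% 3
      if (m < 3) next
      aa <- strsplit(as.character(Biostrings::translate(
        Biostrings::DNAString(substr(ss, f, f + m - 1)))), "")[[1]]
      prev <- 0
      for (st in which(aa == "*")) {
        block <- if (prev + 1 <= st - 1) aa[(prev + 1):(st - 1)] else
          character(0)
        mm <- which(block == "M")
        if (length(mm) && (st - (prev + mm[1])) >= 5)
          oracle[[length(oracle) + 1]] <-
            c(strand = strand, f = f, len = st - (prev + mm[1]))
        prev <- st
      }
    }
  }
  expect_equal(nrow(got), length(oracle))
  expect_equal(sort(got$aa_len),
               sort(as.integer(vapply(oracle, `[[`, character(1), "len"))))
})

test_that("PBS detection finds the tRNA complement and obeys the window", {
  lib <- fixture_library()
  el <- fixture_reference_element()
  downstream <- substr(el$seq, 6426, 6526)
  pbs <- detect_pbs(downstream, lib$trna)
  expect_equal(pbs$trna, "tRNA-Arg")
  expect_equal(pbs$start, 0)
  expect_equal(pbs$length, 14)
  # substring-search oracle
  trna <- lib$trna[["tRNA-Arg"]]
  pat <- revcomp(substr(trna, nchar(trna) - 13, nchar(trna)))
  expect_equal(pbs$start,
               as.integer(regexpr(pat, substr(downstream, 1, 30),
                                  fixed = TRUE)) - 1L)
  # no complement in window -> NULL
  expect_null(detect_pbs(with_seed(85, random_dna(40)), lib$trna))
})

test_that("PPT detection equals exhaustive run enumeration", {
  with_seed(86, {
    up <- paste0(random_dna(38, gc = 0.7), strrep("A", 6), strrep("G", 6))
    ppt <- detect_ppt(up)
    expect_false(is.null(ppt))
    expect_equal(ppt$purine_fraction, 1)
    expect_gte(ppt$end - ppt$start, 10)
    # pyrimidine-rich window -> none
    pyr <- paste(rep(c("C", "T"), 30), collapse = "")
    expect_null(detect_ppt(pyr))
    # oracle: exhaustive enumeration of the best fraction
    region <- substr(up, nchar(up) - 49, nchar(up))
    ch <- strsplit(region, "")[[1]] %in% c("A", "G")
    best <- 0
    for (len in 10:50) for (s in 1:(50 - len + 1)) {
      if (s + len - 1 <= 50) best <- max(best, mean(ch[s:(s + len - 1)]))
    }
    expect_equal(ppt$purine_fraction, best)
  })
})

test_that("dual RNase H copies are counted non-overlapping", {
  lib <- fixture_library()
  el <- fixture_reference_element()
  expect_equal(detect_dual_rnaseh(el$orf_aa[["ORF1"]],
                                  lib$profiles$RNaseH), 2)
  expect_equal(detect_dual_rnaseh(el$orf_aa[["ORF2"]],
                                  lib$profiles$RNaseH), 0)
  # greedy non-overlap oracle on the raw hit list
  hits <- score_pssm(el$orf_aa[["ORF1"]], lib$profiles$RNaseH$pssm,
                     threshold = 30)
  L <- nrow(lib$profiles$RNaseH$pssm)
  hits <- hits[order(-hits$score), ]
  sel <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (!length(sel) || all(abs(hits$pos[i] - hits$pos[sel]) >= L))
      sel <- c(sel, i)
  }
  expect_equal(detect_dual_rnaseh(el$orf_aa[["ORF1"]],
                                  lib$profiles$RNaseH), length(sel))
})

test_that("dot plot shows the LTR repeat and matches brute force", {
  with_seed(87, {
    ltr <- random_dna(300)
    seq <- paste0(ltr, random_dna(900), ltr)
    dp <- dotplot(seq, word = 15)
    # off-diagonal segment at the LTR offset
    off <- dp[dp$strand == "+" & dp$y - dp$x == 1200, ]
    expect_gte(nrow(off), 300 - 15 + 1)
    # symmetry
    key <- paste(dp$x, dp$y, dp$strand)
    expect_true(all(paste(dp$y, dp$x, dp$strand) %in% key))
    # brute-force equality on a small sequence
    s2 <- random_dna(400)
    s2 <- paste0(s2, substr(s2, 50, 120))
    dp2 <- dotplot(s2, word = 15)
    n <- nchar(s2)
    words <- substring(s2, 1:(n - 14), 15:n)
    brute <- list()
    for (i in seq_along(words)) for (j in seq_along(words)) {
      if (words[i] == words[j])
        brute[[length(brute) + 1]] <- c(i, j, "+")
      if (words[i] == revcomp(words[j]))
        brute[[length(brute) + 1]] <- c(i, n - (j + 14) + 1, "-")
    }
    brute <- unique(do.call(rbind, brute))
    got <- unique(dp2[, c("x", "y", "strand")])
    expect_equal(nrow(got), nrow(brute))
    expect_setequal(paste(got$x, got$y, got$strand),
                    paste(brute[, 1], as.integer(brute[, 2]) +
                            ifelse(brute[, 3] == "-", 0, 0), brute[, 3]))
    # random sequence: essentially no off-diagonal direct matches
    s3 <- random_dna(2000)
    dp3 <- dotplot(s3, word = 15)
    expect_lte(nrow(dp3[dp3$strand == "+" & dp3$x != dp3$y, ]), 2)
  })
})

test_that("masking coverage is exact on planted copies and gap-aware", {
  with_seed(88, {
    libseq <- random_dna(2000)
    background <- random_dna(6000)
    genome <- c(chr1 = paste0(substr(background, 1, 3000), libseq,
                              substr(background, 3001, 6000), libseq))
    mask <- mask_coverage(genome, c(lib1 = libseq), max_divergence = 0.2)
    expect_equal(mask$masked_bp, 4000)
    expect_equal(mask$coverage, 4000 / 10000)
    # copies at 30% divergence vanish under a 20% cap
    far <- mutate_dna(libseq, 0.30)
    genome2 <- c(chr1 = paste0(substr(background, 1, 3000), far,
                               substr(background, 3001, 6000)))
    mask2 <- mask_coverage(genome2, c(lib1 = libseq), max_divergence = 0.2)
    expect_lte(mask2$masked_bp, 200)
    # with-gap coverage never exceeds the gap-excluded coverage
    genomeN <- c(chr1 = paste0(strrep("N", 500), genome[["chr1"]]))
    maskN <- mask_coverage(genomeN, c(lib1 = libseq))
    expect_lte(maskN$coverage, maskN$coverage_excl_gaps)
    expect_equal(maskN$gap_bp, 500)
  })
})

test_that("masked bases track the truth annotation at 10% divergence", {
  lib <- fixture_library()
  for (s in 1:10) {
    es <- rt_only_spec(divergence = 0.10, copy_number = 2)
    el <- generate_element(es, seed = 700 + s, library = lib)
    es$master <- el
    gs <- genome_spec(paste0("mk", s), 30000, elements = list(es),
                      seed = 1700 + s, min_spacing = 500)
    g <- generate_genome(gs, library = lib)
    mask <- mask_coverage(g, c(master = el$seq), max_divergence = 0.20)
    truth_bp <- sum(g$truth$copies$end - g$truth$copies$start)
    expect_lte(abs(mask$masked_bp - truth_bp) / truth_bp, 0.02)
  }
})
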