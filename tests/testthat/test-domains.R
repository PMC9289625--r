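# a consensus-like nt string with a planted 2-ODD cassette in frame +1
planted_consensus <- function(seed = 70) {
  lib <- fixture_library()
  with_seed(seed, {
    aa <- paste0(random_aa(50), lib$profiles[["2-ODD"]]$master,
                 random_aa(50))
    paste0(random_dna(0), encode_orf_aa(aa))
  })
}

test_that("a planted cassette is found in the correct frame", {
  lib <- fixture_library()
  hits <- scan_domains(planted_consensus(), lib$profiles)
  odd <- hits[hits$family == "2-ODD", ]
  expect_equal(nrow(odd), 1)
  expect_equal(odd$strand, "+")
  expect_equal(odd$frame, 1)
  expect_equal(odd$aa_start, 51)
})

test_that("element-free random consensuses have no hits", {
  lib <- fixture_library()
  for (s in 1:10) {
    seq <- with_seed(300 + s, random_dna(2000))
    expect_equal(nrow(scan_domains(seq, lib$profiles, threshold = 30)), 0)
  }
})

test_that("domain hit scores equal the window rescoring oracle", {
  lib <- fixture_library()
  seq <- planted_consensus(71)
  hits <- scan_domains(seq, lib$profiles)
  frames <- six_frame_translate(seq)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    aa <- frames$aa[frames$strand == h$strand & frames$frame == h$frame]
    pssm <- lib$profiles[[h$label]]$pssm
    # merged interval: oracle is the max window score inside it
    L <- nrow(pssm)
    starts <- h$aa_start:(h$aa_end - L + 1)
    oracle <- max(vapply(starts, function(p)
      ref_window_score(aa, pssm, p), numeric(1)))
    expect_equal(h$score, oracle, tolerance = 1e-9)
  }
})

test_that("superfamily classification follows the best reference hit", {
  lib <- fixture_library()
  with_seed(72, {
    gy_aa <- paste0(random_aa(30), lib$profiles[["RT_Gypsy"]]$master,
                    random_aa(30))
    gy <- encode_orf_aa(gy_aa)
  })
  call <- classify_superfamily(gy, lib$rt_refs, lib$profiles)
  expect_equal(call$label, "Gypsy")
  expect_false(call$ambiguous)
  # invariance to reverse complement
  call_rc <- classify_superfamily(revcomp(gy), lib$rt_refs, lib$profiles)
  expect_equal(call_rc$label, "Gypsy")
  # no RT -> unclassified
  none <- with_seed(73, random_dna(900))
  expect_equal(classify_superfamily(none, lib$rt_refs, lib$profiles)$label,
               "unclassified")
})

test_that("classification equals an independent argmax over references", {
  lib <- fixture_library()
  with_seed(74, {
    cp_aa <- paste0(random_aa(20), lib$profiles[["RT_Copia"]]$master,
                    random_aa(20))
    cp <- encode_orf_aa(cp_aa)
  })
  call <- classify_superfamily(cp, lib$rt_refs, lib$profiles)
  # oracle: align the full translated frame against every reference
  aa <- six_frame_translate(cp)$aa[1]
  sf <- attr(lib$rt_refs, "superfamily")
  scores <- vapply(names(lib$rt_refs), function(id) {
    Biostrings::score(Biostrings::pairwiseAlignment(
      Biostrings::AAString(aa), Biostrings::AAString(lib$rt_refs[[id]]),
      substitutionMatrix = ltrdomains:::aa_identity_matrix(),
      gapOpening = 4, gapExtension = 1, type = "local"))
  }, numeric(1))
  expect_equal(call$label, unname(sf[names(which.max(scores))]))
  expect_equal(call$label, "Copia")
})

test_that("canonical filtering is a set difference", {
  h <- data.frame(consensus_id = "c", species_id = "s",
                  label = c("RT_Gypsy", "RNaseH", "2-ODD"),
                  family = c("RT", "RNaseH", "2-ODD"),
                  canonical = c(TRUE, TRUE, FALSE), strand = "+", frame = 1,
                  aa_start = 1, aa_end = 10, score = 50)
  expect_equal(filter_canonical(h)$family, "2-ODD")
  expect_equal(nrow(filter_canonical(h[1:2, ])), 0)
  # oracle: plain set difference on families
  canon <- c("GAG", "PR", "RT", "RNaseH", "INT", "Chromo")
  expect_equal(sort(unique(filter_canonical(h)$family)),
               sort(setdiff(unique(h$family), canon)))
})

test_that("profile redundancy collapses to one representative hit", {
  h <- data.frame(consensus_id = "c1", species_id = "s",
                  label = c("AlkB_like_1", "AlkB_like_2", "PMD"),
                  family = c("2-ODD-h1", "2-ODD-h2", "PMD"),
                  canonical = FALSE, strand = "+", frame = 1,
                  aa_start = 1, aa_end = 10, score = c(40, 55, 33))
  map <- c(AlkB_like_1 = "2-ODD", AlkB_like_2 = "2-ODD")
  out <- collapse_profile_families(h, map)
  expect_equal(sort(out$label), c("2-ODD", "PMD"))
  expect_equal(out$score[out$label == "2-ODD"], 55)
  # empty map is the identity transform
  expect_equal(collapse_profile_families(h, character(0)), h)
  # oracle: group by representative, keep max score
  rep_of <- function(l) if (l %in% names(map)) map[[l]] else l
  oracle <- tapply(h$score, vapply(h$label, rep_of, character(1)), max)
  got <- setNames(out$score, out$label)
  expect_equal(unname(got[names(oracle)]), as.numeric(oracle))
})

test_that("the fixation filter counts distinct consensuses per species", {
  mk <- function(n, species = "sp1", fam = "2-ODD") {
    data.frame(consensus_id = paste0(species, "_c", seq_len(n)),
               species_id = species, label = fam, family = fam,
               canonical = FALSE, strand = "+", frame = 1, aa_start = 1,
               aa_end = 10, score = 50)
  }
  r5 <- n_filter_report(mk(5), min_consensuses = 5)
  expect_equal(unname(r5$filtered["sp1", "2-ODD"]), 5)
  r4 <- n_filter_report(mk(4), min_consensuses = 5)
  expect_equal(nrow(r4$filtered), 0)
  expect_equal(unname(r4$unfiltered["sp1", "2-ODD"]), 4)
  # duplicate hits on one consensus count once
  dup <- rbind(mk(5), mk(5))
  expect_equal(unname(n_filter_report(dup)$filtered["sp1", "2-ODD"]), 5)
  # filtered is cell-wise contained in unfiltered
  mixed <- rbind(mk(6), mk(3, fam = "PMD"), mk(2, species = "sp2"))
  rm <- n_filter_report(mixed)
  for (sp in rownames(rm$filtered)) for (fam in colnames(rm$filtered)) {
    expect_lte(rm$filtered[sp, fam], rm$unfiltered[sp, fam])
  }
  # oracle: group-by distinct count
  u <- unique(mixed[, c("species_id", "family", "consensus_id")])
  expect_equal(unname(rm$unfiltered["sp1", "2-ODD"]),
               sum(u$species_id == "sp1" & u$family == "2-ODD"))
})

test_that("cofactor motifs are detected and mutable", {
  pos <- paste0("MAAA", "HAD", strrep("G", 40), "H", "AAAA",
                "RQWERTR", "AAA", "YNF", "AAA")
  rec <- check_cofactor_motifs(pos, distal_h_span = c(30, 90))
  expect_false(is.null(rec$iron_core))
  expect_false(is.null(rec$r_x5_r))
  expect_false(is.null(rec$ynf))
  # positions match a regex oracle
  expect_equal(rec$r_x5_r$pos, as.integer(regexpr("R.{5}R", pos)))
  expect_equal(rec$ynf$pos, as.integer(regexpr("YNF", pos)))
  expect_equal(rec$iron_core$hxd_pos, as.integer(regexpr("H.[DE]", pos)))
  # H -> A mutation in the iron core abolishes the motif
  mut <- sub("HAD", "AAD", pos)
  expect_null(check_cofactor_motifs(mut, distal_h_span = c(30, 90))$iron_core)
  # too-short sequence: all absent
  rec0 <- check_cofactor_motifs("HA")
  expect_null(rec0$iron_core)
  expect_null(rec0$ynf)
})

test_that("the N/Y pair is read off an alignment to a reference block", {
  set.seed(75)
  block <- random_aa(90)
  block <- paste0(substr(block, 1, 39), "N", substr(block, 41, 69), "Y",
                  substr(block, 71, 90))
  query <- paste0(random_aa(10), block, random_aa(10))
  rec <- check_cofactor_motifs(query, reference = list(
    block = block, n_pos = 40, y_pos = 70))
  expect_true(rec$ny_pair$n_conserved)
  expect_true(rec$ny_pair$y_conserved)
  # mutate the aligned N
  query2 <- paste0(random_aa(10), sub("^(.{39})N", "\\1D", block),
                   random_aa(10))
  rec2 <- check_cofactor_motifs(query2, reference = list(
    block = block, n_pos = 40, y_pos = 70))
  expect_false(rec2$ny_pair$n_conserved)
})

test_that("basic-patch scanning matches a brute-force window oracle", {
  polyk <- paste0(strrep("A", 10), strrep("K", 30), strrep("A", 10))
  iv <- scan_basic_patch(polyk, window = 25, kr_fraction = 0.4)
  expect_equal(nrow(iv), 1)
  expect_lte(iv$start, 11)
  expect_gte(iv$end, 40)
  expect_equal(nrow(scan_basic_patch(strrep("ACDEFG", 20))), 0)
  # oracle on a random sequence
  set.seed(76)
  aa <- random_aa(300)
  got <- scan_basic_patch(aa, window = 25, kr_fraction = 0.4)
  ch <- strsplit(aa, "")[[1]]
  fr <- vapply(1:(300 - 24), function(s)
    mean(ch[s:(s + 24)] %in% c("K", "R")), numeric(1))
  hit <- fr >= 0.4
  if (any(hit)) {
    r <- rle(hit)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1
    expect_equal(got$start, s[r$values])
    expect_equal(got$end, e[r$values] + 24)
  } else {
    expect_equal(nrow(got), 0)
  }
})
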