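test_that("element layout matches the requested dimensions", {
  el <- fixture_reference_element()
  expect_equal(nchar(el$seq), 25510)
  ltrs <- el$features[el$features$feature == "long_terminal_repeat", ]
  expect_equal(ltrs$start, c(0, 19085))
  expect_equal(ltrs$end, c(6425, 25510))
  # identical 5'/3' LTRs
  expect_identical(substr(el$seq, 1, 6425), substr(el$seq, 19086, 25510))
  orfs <- el$features[el$features$feature == "ORF", ]
  expect_equal(orfs$end - orfs$start, c(2640, 565) * 3 + 3)
})

test_that("small ORFs span aa_length*3 + 3 nucleotides including the stop", {
  lib <- fixture_library()
  es <- element_spec("Tiny", total_len = 800, ltr_len = 100,
    orf_specs = list(list(orf_id = "O1", aa_length = 10,
                          cassettes = character(0))))
  el <- generate_element(es, seed = 3, library = lib)
  orf <- el$features[el$features$feature == "ORF", ]
  expect_equal(orf$end - orf$start, 33)
})

test_that("infeasible packing raises a sizing error", {
  lib <- fixture_library()
  es <- element_spec("Bad", total_len = 900, ltr_len = 200,
    orf_specs = list(list(orf_id = "O1", aa_length = 400,
                          cassettes = character(0))))
  expect_error(generate_element(es, seed = 1, library = lib), "sizing")
})

test_that("element structural features are laid out as designed", {
  el <- fixture_reference_element()
  lib <- fixture_library()
  f <- el$features
  # PBS immediately 3' of the 5' LTR, antisense to the tRNA 3' end
  pbs <- f[f$feature == "primer_binding_site", ]
  expect_equal(pbs$start, 6425)
  trna <- lib$trna[["tRNA-Arg"]]
  expect_identical(substr(el$seq, pbs$start + 1, pbs$end),
                   revcomp(substr(trna, nchar(trna) - 13, nchar(trna))))
  # PPT immediately 5' of the 3' LTR, purine-rich
  ppt <- f[f$feature == "RR_tract", ]
  expect_equal(ppt$end, 19085)
  ppt_seq <- substr(el$seq, ppt$start + 1, ppt$end)
  expect_gte(mean(strsplit(ppt_seq, "")[[1]] %in% c("A", "G")), 0.9)
  expect_gte(nchar(ppt_seq), 12)
  # terminal inverted repeats at LTR extremities
  ltr <- substr(el$seq, 1, 6425)
  expect_identical(revcomp(substr(ltr, 1, 5)),
                   substr(ltr, 6421, 6425))
  # designed ORFs translate without stops
  expect_false(any(grepl("*", el$orf_aa, fixed = TRUE)))
})

test_that("genome generation is deterministic and honors zero divergence", {
  lib <- fixture_library()
  es <- rt_only_spec(divergence = 0, copy_number = 2)
  gs <- genome_spec("spD", 30000, elements = list(es), seed = 7,
                    min_spacing = 1000)
  g1 <- generate_genome(gs, library = lib)
  g2 <- generate_genome(gs, library = lib)
  expect_identical(g1$fasta, g2$fasta)
  expect_identical(g1$truth, g2$truth)
  # the two copies are identical at divergence zero
  cp <- g1$truth$copies
  seqs <- vapply(seq_len(2), function(i) {
    s <- substr(g1$fasta[["chr1"]], cp$start[i] + 1, cp$end[i])
    if (cp$strand[i] == "-") s <- revcomp(s) else s
  }, character(1))
  expect_identical(seqs[1], seqs[2])
  expect_equal(cp$identity, c(1, 1))
})

test_that("implanted features round-trip exactly at divergence zero", {
  lib <- fixture_library()
  es <- rt_only_spec(divergence = 0, copy_number = 1)
  el <- generate_element(es, seed = 9, library = lib)
  es$master <- el
  gs <- genome_spec("spRT", 20000, elements = list(es), seed = 11)
  g <- generate_genome(gs, library = lib)
  cp <- g$truth$copies[1, ]
  extracted <- substr(g$fasta[["chr1"]], cp$start + 1, cp$end)
  if (cp$strand == "-") extracted <- revcomp(extracted)
  expect_identical(extracted, el$seq)
  # every sub-feature re-extracts to its master sequence
  ft <- g$truth$features
  for (i in seq_len(nrow(ft))) {
    gseq <- substr(g$fasta[["chr1"]], ft$start[i] + 1, ft$end[i])
    if (ft$strand[i] == "-") gseq <- revcomp(gseq)
    mrow <- el$features[el$features$label == ft$label[i] &
                        el$features$feature == ft$feature[i], ][1, ]
    expect_identical(gseq, substr(el$seq, mrow$start + 1, mrow$end))
  }
})

test_that("empty element list yields pure background and empty truth", {
  gs <- genome_spec("bg", 5000, elements = list(), seed = 2)
  g <- generate_genome(gs)
  expect_equal(nchar(g$fasta[["chr1"]]), 5000)
  expect_equal(nrow(g$truth$copies), 0)
})

test_that("gap runs are written as N and cannot overlap elements", {
  gs <- genome_spec("gap", 5000, elements = list(), seed = 2,
                    gap_runs = list(c(1000, 50)))
  g <- generate_genome(gs)
  expect_identical(substr(g$fasta[["chr1"]], 1001, 1050),
                   strrep("N", 50))
})

test_that("realized divergence matches the binomial expectation", {
  lib <- fixture_library()
  es <- rt_only_spec(divergence = 0.05, copy_number = 6)
  gs <- genome_spec("spB", 40000, elements = list(es), seed = 13,
                    min_spacing = 500)
  g <- generate_genome(gs, library = lib)
  # substitution model: per-site change prob = rate (always to another base)
  p <- 0.05
  L <- 3200
  se <- sqrt(p * (1 - p) / L)
  div <- 1 - g$truth$copies$identity
  expect_true(all(abs(div - p) <= 3 * se + 1e-9))
})

test_that("copies at 2% divergence stay above 94% pairwise identity", {
  lib <- fixture_library()
  es <- rt_only_spec(divergence = 0.02, copy_number = 4)
  gs <- genome_spec("spP", 30000, elements = list(es), seed = 17,
                    min_spacing = 500)
  g <- generate_genome(gs, library = lib)
  cp <- g$truth$copies
  seqs <- vapply(seq_len(nrow(cp)), function(i) {
    s <- substr(g$fasta[["chr1"]], cp$start[i] + 1, cp$end[i])
    if (cp$strand[i] == "-") revcomp(s) else s
  }, character(1))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_gte(global_identity(seqs[i], seqs[j]), 0.94)
  }
})

test_that("profile library carries the requested flags and structure", {
  lib <- fixture_library()
  specs <- default_domain_specs()
  expect_equal(length(lib$profiles), nrow(specs))
  canon <- vapply(lib$profiles, `[[`, logical(1), "canonical")
  expect_equal(unname(canon), specs$canonical)
  # consensus residue scores highest in every column
  pr <- lib$profiles[["2-ODD"]]
  master_idx <- match(strsplit(pr$master, "")[[1]], colnames(pr$pssm))
  expect_equal(apply(pr$pssm, 1, which.max), master_idx)
  expect_true(all(is.finite(pr$pssm)))
  # the master scores the maximal attainable score
  self <- score_pssm(pr$master, pr$pssm)
  expect_equal(max(self$score), pssm_max_score(pr$pssm))
  # reference RT library: >= 2 per superfamily, tRNA-Arg present
  sf <- attr(lib$rt_refs, "superfamily")
  expect_true(all(table(sf) >= 2))
  expect_true("tRNA-Arg" %in% names(lib$trna))
  # the 2-ODD master carries the AlkB cofactor motifs
  rec <- check_cofactor_motifs(pr$master)
  expect_false(is.null(rec$iron_core))
  expect_false(is.null(rec$r_x5_r))
  expect_false(is.null(rec$ynf))
})

test_that("binding series realizes the Hill isotherm", {
  bs <- generate_binding_series(kd = 0.5, hill_n = 1, concentrations = 0.5)
  # theta = 0.5 at P = Kd: free = total/2
  expect_equal(bs$free[2], attr(bs, "total") / 2)
  bs2 <- generate_binding_series(kd = 0.5, hill_n = 1,
                                 concentrations = 1e-8)
  expect_equal(bs2$free[2], attr(bs2, "total"), tolerance = 1e-6)
  expect_error(generate_binding_series(kd = -1, concentrations = 1),
               "positive")
  # noise-free Hill plot is exactly linear with slope 1
  conc <- c(0.02, 0.05, 0.1, 0.25, 0.5, 1, 2)
  bs3 <- generate_binding_series(kd = 0.21, hill_n = 1,
                                 concentrations = conc)
  th <- fraction_bound(bs3)
  y <- log10(th$theta / (1 - th$theta))
  x <- log10(th$conc)
  fit <- lm(y ~ x)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 1e-9)
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-9)
})

test_that("chromatograms realize requested m6A/A ratios", {
  ch <- generate_chromatogram(c(ctrl = 0.1, zero = 0))
  w <- list(G = c(1.5, 2.5), A = c(3.5, 4.5), m6A = c(5.5, 6.5))
  a <- integrate_peaks(ch$ctrl, w)
  expect_equal(m6a_ratio(a), 0.1, tolerance = 0.01)
  # zero ratio: no m6A signal above baseline
  a0 <- integrate_peaks(ch$zero, w)
  expect_lt(abs(a0[["m6A"]]), 0.01 * a0[["A"]])
})

test_that("generators are deterministic given spec and seed", {
  lib <- fixture_library()
  expect_identical(generate_profile_library(seed = 5),
                   generate_profile_library(seed = 5))
  es <- gypsy_spec()
  expect_identical(generate_element(es, seed = 4, library = lib),
                   generate_element(es, seed = 4, library = lib))
  expect_identical(
    generate_binding_series(0.2, 1, c(0.1, 1), noise_sd = 0.05, seed = 3),
    generate_binding_series(0.2, 1, c(0.1, 1), noise_sd = 0.05, seed = 3))
  expect_identical(generate_chromatogram(c(a = 0.2), seed = 8),
                   generate_chromatogram(c(a = 0.2), seed = 8))
})
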