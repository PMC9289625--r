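# Shared fixtures, built once per test run and memoized.

.fix <- new.env(parent = emptyenv())

fixture_library <- function() {
  if (is.null(.fix$lib)) .fix$lib <- generate_profile_library(seed = 42)
  .fix$lib
}

# compact Gypsy-like family spec carrying a 2-ODD extra ORF
gypsy_spec <- function(family_id = "GypA", divergence = 0.02,
                       copy_number = 6) {
  element_spec(family_id, total_len = 7000, ltr_len = 400,
    orf_specs = list(
      list(orf_id = "ORF1", aa_length = 1400,
           cassettes = c("GAG", "PR", "RT_Gypsy", "RNaseH", "RNaseH",
                         "INT")),
      list(orf_id = "ORF2", aa_length = 300, cassettes = c("2-ODD"))),
    divergence = divergence, copy_number = copy_number)
}

# plain Copia-like family (canonical domains only)
copia_spec <- function(family_id = "CopA", divergence = 0.02,
                       copy_number = 6) {
  element_spec(family_id, total_len = 6000, ltr_len = 350,
    orf_specs = list(
      list(orf_id = "ORF1", aa_length = 1300,
           cassettes = c("GAG", "PR", "INT", "RT_Copia", "RNaseH"))),
    divergence = divergence, copy_number = copy_number)
}

# minimal RT-only family for fast scan tests
rt_only_spec <- function(family_id = "Min", divergence = 0,
                         copy_number = 1) {
  element_spec(family_id, total_len = 3200, ltr_len = 250,
    orf_specs = list(
      list(orf_id = "ORF1", aa_length = 600, cassettes = c("RT_Gypsy"))),
    divergence = divergence, copy_number = copy_number)
}

# the reference element built to the printed worked-example dimensions
reference_element_spec <- function() {
  element_spec("GypRef", total_len = 25510, ltr_len = 6425,
    orf_specs = list(
      list(orf_id = "ORF1", aa_length = 2640,
           cassettes = c("GAG", "PR", "RT_Gypsy", "RNaseH", "RNaseH",
                         "INT", "Chromo")),
      list(orf_id = "ORF2", aa_length = 565, cassettes = c("2-ODD"))),
    divergence = 0, copy_number = 1)
}

fixture_reference_element <- function() {
  if (is.null(.fix$ref_el))
    .fix$ref_el <- generate_element(reference_element_spec(), seed = 1,
                                    library = fixture_library())
  .fix$ref_el
}

# independent full (unbanded) affine-gap pairwise DP, mirroring the
# engine's gap convention (opening a gap costs gap_open + gap_ext)
ref_affine_score <- function(a, b, match = 1, mismatch = -1,
                             gap_open = -5, gap_ext = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1); X <- M; Y <- M
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- gap_open + gap_ext * i
  for (j in seq_len(m)) Y[1, j + 1] <- gap_open + gap_ext * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (a[i] == b[j]) match else mismatch
    M[i + 1, j + 1] <- s + max(M[i, j], X[i, j], Y[i, j])
    X[i + 1, j + 1] <- max(M[i, j + 1] + gap_open + gap_ext,
                           X[i, j + 1] + gap_ext,
                           Y[i, j + 1] + gap_open + gap_ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] + gap_open + gap_ext,
                           X[i + 1, j] + gap_open + gap_ext,
                           Y[i + 1, j] + gap_ext)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force PSSM window score at a given aa position (1-based)
ref_window_score <- function(aa, pssm, pos) {
  ch <- strsplit(aa, "")[[1]]
  L <- nrow(pssm)
  sum(vapply(seq_len(L), function(i) {
    r <- ch[pos + i - 1]
    if (r == "*") return(-4)
    j <- match(r, colnames(pssm))
    if (is.na(j)) 0 else pssm[i, j]
  }, numeric(1)))
}
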