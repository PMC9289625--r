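DNA_BASES4 <- c("A", "C", "G", "T")
AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Evaluate code with a fixed RNG seed, restoring the caller's RNG state
#' @param seed integer seed
#' @param code expression to evaluate
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Random DNA string with a given GC content
#' @param n length in nucleotides
#' @param gc GC fraction
#' @return character scalar
#' @export
random_dna <- function(n, gc = 0.4) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES4, n, replace = TRUE, prob = p), collapse = "")
}

random_aa <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")

#' Reverse complement of a DNA string
#' @param x DNA string (may contain N)
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

split1 <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

#' Point-substitute a DNA string at a given per-site rate
#'
#' Substitutions are iid; a substituted site always changes to a different
#' base. N positions are left untouched.
#' @param seq DNA string
#' @param rate per-site substitution probability
#' @return mutated string
#' @export
mutate_dna <- function(seq, rate) {
  if (rate <= 0 || nchar(seq) == 0) return(seq)
  ch <- split1(seq)
  hit <- which(runif(length(ch)) < rate & ch != "N")
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(b) {
      sample(setdiff(DNA_BASES4, b), 1)
    }, character(1))
  }
  paste(ch, collapse = "")
}

#' Point-substitute an amino-acid string at a given per-site rate
#' @param aa amino-acid string
#' @param rate per-site substitution probability
#' @export
mutate_aa <- function(aa, rate) {
  if (rate <= 0 || nchar(aa) == 0) return(aa)
  ch <- split1(aa)
  hit <- which(runif(length(ch)) < rate)
  if (length(hit)) {
    ch[hit] <- vapply(ch[hit], function(a) sample(setdiff(AA20, a), 1),
                      character(1))
  }
  paste(ch, collapse = "")
}

# integer coding used by the C++ engines ------------------------------------

.aa_lookup <- local({
  tab <- rep(-1L, 128)
  tab[utf8ToInt("*") + 1L] <- -2L
  for (i in seq_along(AA20)) tab[utf8ToInt(AA20[i]) + 1L] <- i - 1L
  tab
})

.dna_lookup <- local({
  tab <- rep(-1L, 128)
  for (i in seq_along(DNA_BASES4)) tab[utf8ToInt(DNA_BASES4[i]) + 1L] <- i - 1L
  tab
})

aa_to_int <- function(aa) .aa_lookup[utf8ToInt(aa) + 1L]
dna_to_int <- function(seq) .dna_lookup[utf8ToInt(seq) + 1L]

#' Fraction of identical positions between two equal-length strings
#' @keywords internal
hamming_identity <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (nchar(a) == 0) return(1)
  mean(utf8ToInt(a) == utf8ToInt(b))
}

# codon machinery ------------------------------------------------------------

codons_for_aa <- function() {
  if (!is.null(the$codon_table)) return(the$codon_table)
  gc <- Biostrings::GENETIC_CODE
  non_stop <- gc[gc != "*"]
  the$codon_table <- split(names(non_stop), non_stop)
  the$codon_table
}

#' Encode an amino-acid string as DNA by sampling synonymous codons
#'
#' Stop codons can never arise inside the run; the designed reading frame is
#' stop-free by construction.
#' @param aa amino-acid string (20-letter alphabet)
#' @return DNA string of length 3*nchar(aa)
#' @keywords internal
encode_orf_aa <- function(aa) {
  tab <- codons_for_aa()
  ch <- split1(aa)
  cods <- vapply(ch, function(a) {
    opts <- tab[[a]]
    if (is.null(opts)) stop("cannot encode residue '", a, "'")
    if (length(opts) == 1) opts else sample(opts, 1)
  }, character(1))
  paste(cods, collapse = "")
}
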