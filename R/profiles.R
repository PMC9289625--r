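#' Build a log-odds PSSM from a single master amino-acid sequence
#'
#' Columns hold, for each of the 20 residues, log2 of the ratio between the
#' pseudocount-smoothed emission probability and the uniform background
#' (1/20). With the default pseudocount of 1, the master residue scores
#' log2(10.5) ~ 3.39 bits and every other residue -1 bit, so profile scores
#' are additive bit scores.
#'
#' @param master amino-acid string the profile is built from
#' @param pseudocount total pseudocount mass spread uniformly over residues
#' @return numeric matrix, length(master) rows x 20 columns (columns ordered
#'   as `AA20`), with the master sequence attached as an attribute
#' @export
build_pssm <- function(master, pseudocount = 1) {
  ch <- split1(master)
  L <- length(ch)
  q <- 1 / 20
  m <- matrix(log2((pseudocount * q) / (1 + pseudocount) / q), L, 20,
              dimnames = list(NULL, AA20))
  hit <- match(ch, AA20)
  if (anyNA(hit)) stop("master sequence contains non-standard residues")
  m[cbind(seq_len(L), hit)] <- log2(((1 + pseudocount * q) / (1 + pseudocount)) / q)
  attr(m, "master") <- master
  m
}

#' Score an amino-acid sequence against a PSSM, one window per position
#'
#' Thin wrapper over the compiled window scanner. Unknown residues (X) score
#' 0; stop codons score `stop_score`.
#'
#' @param aa amino-acid string
#' @param pssm matrix from [build_pssm()]
#' @param threshold minimum reported score (bits)
#' @param stop_score score assigned to a stop codon inside a window
#' @return data.frame with `pos` (1-based window start on `aa`) and `score`
#' @export
score_pssm <- function(aa, pssm, threshold = -Inf, stop_score = -4) {
  r <- pssm_scan_cpp(aa_to_int(aa), pssm, threshold, 0, stop_score)
  data.frame(pos = r$pos, score = r$score)
}

#' Maximum attainable score of a PSSM
#' @param pssm matrix from [build_pssm()]
#' @export
pssm_max_score <- function(pssm) sum(apply(pssm, 1, max))

#' Default domain profile specification table
#'
#' The canonical set covers the domains every plant LTR retrotransposon
#' carries (GAG, protease, RT, RNase H, integrase, Chromo); the non-canonical
#' set covers the extra domains the discovery screen is after (2-ODD/AlkB,
#' PMD, G-patch, AIR1). RT gets one profile per superfamily of interest so
#' that both Gypsy- and Copia-derived elements are found by the same scan.
#'
#' @return data.frame with columns label, family, length_aa, canonical,
#'   superfamily (NA except for RT profiles)
#' @export
default_domain_specs <- function() {
  data.frame(
    label = c("GAG", "PR", "RT_Gypsy", "RT_Copia", "RNaseH", "INT", "Chromo",
              "2-ODD", "PMD", "G-patch", "AIR1"),
    family = c("GAG", "PR", "RT", "RT", "RNaseH", "INT", "Chromo",
               "2-ODD", "PMD", "G-patch", "AIR1"),
    length_aa = c(120L, 100L, 200L, 200L, 130L, 150L, 60L,
                  180L, 150L, 50L, 60L),
    canonical = c(rep(TRUE, 7), rep(FALSE, 4)),
    superfamily = c(NA, NA, "Gypsy", "Copia", rep(NA, 7)),
    stringsAsFactors = FALSE
  )
}

# write the AlkB-family cofactor motifs into a synthetic 2-ODD master:
# HxD with a distal H (iron core), RxxxxxR (2-OG), YNF (m6A recognition)
implant_alkb_motifs <- function(aa) {
  ch <- split1(aa)
  n <- length(ch)
  stopifnot(n >= 160)
  ch[20] <- "R"; ch[26] <- "R"
  ch[60] <- "H"; ch[62] <- "D"
  ch[120] <- "H"
  ch[n - 30] <- "Y"; ch[n - 29] <- "N"; ch[n - 28] <- "F"
  paste(ch, collapse = "")
}

#' Generate a synthetic profile library, RT reference set and tRNA library
#'
#' Each profile is a log-odds PSSM built from a random master amino-acid
#' sequence. The RT reference library carries at least two noisy copies of a
#' distinct RT master per superfamily label (Copia, Gypsy, DIRS, ERV,
#' Caulimoviridae, LINE); the Gypsy and Copia RT masters are shared with the
#' corresponding scan profiles so that synthetic elements built from those
#' profiles classify correctly. The 2-ODD master carries the AlkB-family
#' cofactor motifs (HxD...H iron core, RxxxxxR, YNF) so that motif checks on
#' discovered consensus sequences behave as they would on a real AlkB
#' domain. The tRNA library always includes tRNA-Arg.
#'
#' @param domain_specs data.frame as returned by [default_domain_specs()]
#' @param seed integer seed
#' @param refs_per_superfamily reference RT sequences per superfamily
#' @param ref_noise per-residue substitution rate applied to reference copies
#' @return list with elements `profiles` (named list; each has label, family,
#'   canonical, master, pssm), `rt_refs` (named character vector of aa
#'   sequences with a `superfamily` attribute vector), `trna` (named character
#'   vector of tRNA DNA sequences)
#' @export
generate_profile_library <- function(domain_specs = default_domain_specs(),
                                     seed = 1,
                                     refs_per_superfamily = 2,
                                     ref_noise = 0.05) {
  with_seed(seed, {
    superfams <- c("Copia", "Gypsy", "DIRS", "ERV", "Caulimoviridae", "LINE")
    rt_masters <- setNames(
      vapply(superfams, function(s) random_aa(200), character(1)), superfams)

    profiles <- vector("list", nrow(domain_specs))
    names(profiles) <- domain_specs$label
    for (i in seq_len(nrow(domain_specs))) {
      sp <- domain_specs[i, ]
      master <- if (!is.na(sp$superfamily) && sp$family == "RT")
        rt_masters[[sp$superfamily]] else random_aa(sp$length_aa)
      if (sp$family == "2-ODD") master <- implant_alkb_motifs(master)
      profiles[[i]] <- list(label = sp$label, family = sp$family,
                            canonical = sp$canonical, master = master,
                            pssm = build_pssm(master))
    }

    refs <- character(0)
    ref_lab <- character(0)
    for (s in superfams) {
      for (r in seq_len(refs_per_superfamily)) {
        refs <- c(refs, mutate_aa(rt_masters[[s]], ref_noise))
        ref_lab <- c(ref_lab, s)
      }
    }
    names(refs) <- paste0(ref_lab, "_ref", ave(seq_along(ref_lab), ref_lab,
                                               FUN = seq_along))
    attr(refs, "superfamily") <- setNames(ref_lab, names(refs))

    trna <- setNames(
      vapply(1:3, function(i) random_dna(76, gc = 0.5), character(1)),
      c("tRNA-Arg", "tRNA-Met", "tRNA-Lys"))

    list(profiles = profiles, rt_refs = refs, trna = trna)
  })
}
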