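#' Extract the amino-acid region of a profile hit from a consensus
#'
#' @param consensus `consensus_record` or nt string
#' @param profile a single profile object
#' @param threshold scan threshold (bits)
#' @return amino-acid string of the best-scoring hit window
#' @export
extract_domain_region <- function(consensus, profile, threshold = 30) {
  hits <- scan_domains(consensus, list(profile), threshold)
  if (!nrow(hits))
    stop("no hit to profile '", profile$label, "' on this consensus")
  h <- hits[1, ]
  seq <- if (inherits(consensus, "consensus_record")) consensus$seq else
    consensus
  frames <- six_frame_translate(seq)
  aa <- frames$aa[frames$strand == h$strand & frames$frame == h$frame]
  substr(aa, h$aa_start, h$aa_end)
}

#' Poisson-corrected amino-acid distance matrix from an alignment
#'
#' p is the mismatch fraction over columns where both rows are non-gap;
#' d = -(19/20) * ln(1 - 20 p / 19), capped at 5 (and flagged) when the pair
#' is saturated.
#'
#' @param aln `msa` object, character matrix, or named character vector of
#'   equal-length aligned amino-acid sequences
#' @return symmetric numeric matrix with a `saturated` logical matrix
#'   attribute
#' @export
build_distance_matrix <- function(aln) {
  m <- if (inherits(aln, "msa")) aln$matrix else
    if (is.matrix(aln)) aln else {
      stopifnot(length(unique(nchar(aln))) == 1)
      do.call(rbind, lapply(aln, split1))
    }
  n <- nrow(m)
  stopifnot(n >= 3)
  labs <- rownames(m)
  if (is.null(labs)) labs <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(labs, labs))
  sat <- matrix(FALSE, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- m[i, ] != "-" & m[j, ] != "-"
    if (!any(ok))
      stop("no comparable sites between '", labs[i], "' and '", labs[j], "'")
    p <- mean(m[i, ok] != m[j, ok])
    if (p >= 19 / 20) {
      d[i, j] <- d[j, i] <- 5
      sat[i, j] <- sat[j, i] <- TRUE
    } else {
      d[i, j] <- d[j, i] <- min(5, -(19 / 20) * log(1 - 20 * p / 19))
    }
  }
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining (via ape); deterministic given the matrix.
#' @param dm symmetric distance matrix with labels
#' @return `phylo` tree (unrooted)
#' @export
nj_tree <- function(dm) {
  stopifnot(nrow(dm) >= 3)
  ape::nj(as.dist(dm))
}

#' Bootstrap support for the NJ tree of an amino-acid alignment
#'
#' Columns are resampled with replacement; a distance NJ tree is rebuilt per
#' replicate and bipartition recovery is counted on the point-estimate tree.
#' Supports are percentages stored in `node.label`.
#'
#' @param aln alignment accepted by [build_distance_matrix()]
#' @param n_replicates bootstrap replicates (0 = no supports)
#' @param seed integer seed
#' @return list with `tree` (point estimate, node labels = supports when
#'   requested) and `supports` (numeric vector or NULL)
#' @export
bootstrap_support <- function(aln, n_replicates = 100, seed = 1) {
  m <- if (inherits(aln, "msa")) aln$matrix else
    if (is.matrix(aln)) aln else do.call(rbind, lapply(aln, split1))
  tree <- nj_tree(build_distance_matrix(m))
  if (n_replicates == 0) return(list(tree = tree, supports = NULL))
  reps <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
      nj_tree(build_distance_matrix(m[, cols, drop = FALSE]))
    })
  })
  counts <- ape::prop.clades(tree, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0
  supports <- round(100 * counts / n_replicates)
  tree$node.label <- as.character(supports)
  list(tree = tree, supports = supports)
}

#' Report the placement of a query leaf among labeled reference groups
#'
#' On the tree rooted at the declared outgroup, finds the smallest reference
#' group whose minimal clade with the query contains no other group's
#' members ("nested within"), and names the sister group of that clade.
#' Tips belonging to no reference group (for example, other query leaves) do
#' not veto a placement. A placement whose clade support is below 50 is
#' flagged unresolved.
#'
#' @param tree `phylo` tree (node labels holding bootstrap percentages are
#'   used when present)
#' @param query_label query leaf label
#' @param reference_groups named list of character vectors (group -> labels)
#' @param outgroup leaf label(s) to root on
#' @return list of class `placement_report`: `within`, `sister`, `support`,
#'   `unresolved`
#' @export
place_query <- function(tree, query_label, reference_groups, outgroup) {
  if (!query_label %in% tree$tip.label) stop("query leaf not in tree")
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE,
                      edgelabel = TRUE)
  grp_of <- unlist(lapply(names(reference_groups), function(g)
    setNames(rep(g, length(reference_groups[[g]])), reference_groups[[g]])))
  best <- NULL
  for (g in names(reference_groups)) {
    members <- intersect(reference_groups[[g]], rooted$tip.label)
    if (!length(members)) next
    node <- ape::getMRCA(rooted, c(members, query_label))
    if (is.null(node)) next
    tips <- ape::extract.clade(rooted, node)$tip.label
    other <- setdiff(names(grp_of), members)
    if (!any(tips %in% other)) {
      if (is.null(best) || length(members) < length(best$members))
        best <- list(group = g, members = members, node = node)
    }
  }
  if (is.null(best))
    return(structure(list(within = NA_character_, sister = NA_character_,
                          support = NA_real_, unresolved = TRUE),
                     class = "placement_report"))
  # sister clade of the placement node
  edge <- rooted$edge
  parent <- edge[edge[, 2] == best$node, 1]
  sister_label <- NA_character_
  if (length(parent)) {
    sibs <- edge[edge[, 1] == parent, 2]
    sibs <- setdiff(sibs, best$node)
    sis_tips <- unlist(lapply(sibs, function(s) {
      if (s <= length(rooted$tip.label)) rooted$tip.label[s] else
        ape::extract.clade(rooted, s)$tip.label
    }))
    sis_groups <- grp_of[intersect(sis_tips, names(grp_of))]
    if (length(sis_groups)) {
      tb <- sort(table(sis_groups), decreasing = TRUE)
      sister_label <- names(tb)[1]
    }
  }
  support <- NA_real_
  if (!is.null(rooted$node.label)) {
    nl <- suppressWarnings(as.numeric(
      rooted$node.label[best$node - length(rooted$tip.label)]))
    support <- nl
  }
  structure(list(within = best$group, sister = sister_label,
                 support = support,
                 unresolved = !is.na(support) && support < 50),
            class = "placement_report")
}
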