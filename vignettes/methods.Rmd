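---
title: "Discovering fixed non-canonical domains in LTR retrotransposons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering fixed non-canonical domains in LTR retrotransposons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ltrdomains` is a desk-scale, database-free implementation of a discovery
screen for protein domains fixed in plant LTR retrotransposons, together
with the analytics used to validate a discovered RNA-demethylase-like
protein. This vignette explains the models behind each stage, the
parameters that matter, what the synthetic data generator does and does not
emulate, and the numerical choices made where the design was open.

## The discovery model

LTR retrotransposons carry a conserved backbone of domains (GAG, protease,
RT, RNase H, integrase, and in chromoviruses a Chromo domain). The screen
asks: which *other* conserved domains appear repeatedly inside these
elements? Its unit of evidence is the **family consensus**: copies of one
element family are aligned and majority-called, so that a domain present in
the consensus was present in the family's ancestor rather than in one
insertion. Fixation is then asserted with the **n5 filter**: a non-canonical
domain is reported for a species only when it occurs in at least five
consensus sequences from that species (one consensus corresponds to one
family or subfamily). Requiring repeated, independent consensus support is
what separates an evolutionarily retained acquisition from a one-off
insertion artifact.

The discovery chain, per species genome:

1. **RT anchoring.** Amino-acid PSSMs are slid over all six reading frames.
   A window scoring at or above the threshold (default 30 bits) becomes a
   raw hit; overlapping projections merge, keeping the best score. Merged
   spans must measure 520–840 bp, inclusive — the coding span of an RT
   domain.
2. **Redundancy control.** Per species, RT sequences are clustered greedily
   at 95% global-alignment identity; at most 50 members per cluster are
   carried forward.
3. **Locus extension.** Hits grow ±5 kb (clamped at contig ends);
   minus-strand loci are reverse-complemented. Note the consequence: any
   element longer than ~11.6 kb cannot be reconstructed in full from one
   locus — giant elements come out truncated at this stage, which is why
   full-length characterization is a separate module.
4. **Family clustering and consensus.** Loci cluster greedily when a local
   alignment covers at least half of the shorter sequence at 80% identity or
   better; clusters of five or more loci are aligned progressively and
   majority-called over match columns (non-gap fraction at least 0.5,
   boundary inclusive; residue ties break alphabetically, a fixed and
   documented rule).
5. **Annotation.** Consensuses are scanned against the whole profile
   library; same-family overlapping hits merge; redundant homologous
   profiles collapse to one representative per family; hits to the six
   canonical families are removed; the rest are tabulated per species and
   passed through the n-filter (a parameter, default 5, so the unfiltered
   view is the same code path).

Superfamily classification scores the translated RT region of each
consensus against a labeled reference RT library (local alignment) and takes
the label of the best score; the fixed tie order is Copia, Gypsy, DIRS, ERV,
Caulimoviridae, LINE, and margins below 1 are flagged ambiguous rather than
silently resolved.

## The synthetic study system

The generator produces the inputs the pipeline assumes, with ground truth:

* **Elements** are laid out `LTR — PBS — ORFs with padding — PPT — LTR`.
  LTRs are identical on the master and begin/end with a TG…CA terminal
  inverted repeat. The PBS is the reverse complement of the 3'-terminal
  14 nt of a named tRNA (configurable 12–18 nt; the biological statement
  "antisense to tRNA-Arg" fixes the tRNA, not the length). ORFs are
  stop-free codon runs embedding domain cassettes sampled from the profile
  masters with 2% amino-acid noise; each upstream pad ends with an in-frame
  stop so the designed ATG→stop span is maximal.
* **Genomes** are iid background at a chosen GC with copies implanted by
  randomized slot placement (guaranteeing non-overlap and spacing), each
  copy mutated by iid substitutions at the family's divergence rate, strand
  chosen at random, N-gap runs written last. Divergence is
  substitution-only by default; short indels confined to internal padding
  are an opt-in flag, kept for LTR-boundary edge-case testing.
* **Lineage structure.** `derive_subfamily()` mutates a family master
  (default scenario: 15% per subfamily) to model an old lineage that
  diversified after capturing a domain. The derived master keeps its two
  LTRs identical: replication copies both LTRs from one template, so
  LTR-pair identity resets at every insertion however far the lineage has
  diverged — without this, subfamily copies would present decayed LTR pairs
  no detector (and no real element) would show at insertion time. This is the situation that makes
  the n5 filter meaningful: five subfamilies of six copies each yield five
  separate consensuses all carrying the captured domain. A single family,
  however many its copies, yields one consensus and can never pass a
  five-consensus fixation criterion — the filter is counting independent
  fixation evidence, not copy number.
* **Profiles** are single-master log-odds PSSMs with uniform pseudocounts
  (master residue ≈ 3.39 bits, others −1 bit). The scan threshold of 30
  bits was set where element-free synthetic genomes produce zero hits
  across seeds while implanted domains at 10% nucleotide divergence score
  in the hundreds of bits; there is no sharp trade-off anywhere near it.
* **Biochemical fixtures.** Binding series follow θ(P) = P^n/(Kd^n + P^n)
  with truncated Gaussian noise on θ and record free-RNA signal per lane
  plus a zero-protein lane; chromatograms are Gaussian peaks for G, A and
  m6A at fixed retention times whose areas realize a requested m6A/A ratio.

What the generator does **not** emulate: nested or fragmented insertions,
solo LTRs, repeat-rich background, CpG-structured substitution processes,
codon bias, or sequencing artifacts. Passing tests therefore demonstrate
that the pipeline's logic is correct under its own assumptions — clean
multi-copy families in neutral background — not that its thresholds are
optimal on real assemblies.

## Full-length characterization

The LTR-pair detector seeds on exact 20-mers whose offset lies between 5
and 20 kb (the offset is measured between LTR *start* positions, the
LTRharvest convention), extends the per-position match vector outward from
the seed span (match +1 / mismatch −3, boundary at the running-score
maximum) and snaps boundaries to TG…CA termini within ±5 nt — candidates
supported by both repeat copies take priority, with a single-copy fallback
because one copy's motif may be mutated. Repeat length must fall in
[100, 3000] nt by default and identity at or above 0.85; overlapping
candidates resolve by identity × length. The defaults k = 20 and identity
0.85 were chosen so that element-free genomes yield zero pairs across
seeds.

One documented conflict: the reference giant element carries 6,425 bp LTRs,
which the stock 3 kb length cap rejects — the same tension present in the
original tool settings. The package keeps the cap faithful and demonstrates
recovery at a raised cap (7 kb) in its worked example, rather than guessing
an undocumented recovery path.

ORF calling requires ATG starts (an any-start flag exists because ORF
delimitation conventions vary); reported lengths exclude the stop. PBS
detection searches a 30 nt window downstream of the 5' LTR for the reverse
complement of any library tRNA's 3'-terminal ≥ 12 nt, preferring longer and
more LTR-proximal matches. PPT detection picks the highest-purine-fraction
run of length ≥ 10 within a 50 nt window upstream of the 3' LTR (ties:
longer, then closer to the LTR). Masking accepts seed-and-extend local
alignments whose divergence (1 − matches/alignment-length, gaps counting
against) is at most 20%, merges intervals, and reports coverage over the
full assembly and excluding N runs; CpG-adjusted Kimura divergence is out
of scope.

## Phylogenetics

Maximum-likelihood inference is deliberately replaced by Poisson-corrected
neighbor joining: the package's claims are about pipeline mechanics and
qualitative placement (is the query nested among the Gypsy references?
which group is its sister?), not about likelihood-based branch support.
Distances are d = −(19/20)·ln(1 − 20p/19) on pairwise mismatch fractions
over shared non-gap columns, capped at 5 and flagged when saturated. NJ is
exact on additive matrices (a tested property). Bootstrap resamples
alignment columns with replacement, rebuilds the NJ tree per replicate and
counts bipartition recovery on the point estimate; supports are
percentages. Trees are unrooted; placement reports require the caller to
declare an outgroup, as no rooting convention is implied by the data.

## Biochemical estimators

The Hill transformation linearizes the binding isotherm:
log10(θ/(1−θ)) = n·log10(c) − n·log10(Kd), so an ordinary least-squares
line gives the Hill coefficient (slope) and Kd = 10^(−intercept/slope).
Lanes with θ outside (0, 0.999) carry no information for the logit and are
excluded *and reported*; θ is clamped at 0.999 to avoid infinities. The
regression is unweighted, on replicate means. A non-positive slope is
rejected as non-binding data rather than returned. Mass-to-molar conversion
(ng per µL and kDa to µM) is exact unit algebra; the protein's molecular
weight is a required user input because no single value is implied by the
assay description.

Chromatogram quantification subtracts a median out-of-window baseline,
integrates trapezoidally inside non-overlapping retention-time windows (or
sums peak-list areas by center), forms m6A/A, and reports percent
demethylation against the no-protein control,
100·(1 − ratio_sample/ratio_control). Since only ratios of areas matter,
the result is invariant to common rescaling — the property that makes the
percentage comparable across runs.

Recovery set-points used throughout the tests: a dissociation constant of
0.21 µM (recovered exactly from noise-free series, and within 5% in median
over 1,000 replicates at 2% noise), and demethylation of 60% and 75%
(sample/control ratio 0.40 and 0.25). A "dead mutant" fixture — control-level
m6A ratio with intact binding — expresses the dissociation of catalysis
from binding as a test.

## Numerical choices and problem sizes

* Pairwise global identity is matches over all alignment columns
  (Needleman–Wunsch, match 1 / mismatch −1 / gap open −5 / extend −1); this
  is a deliberate, documented definition rather than a reproduction of any
  particular clustering tool's internal identity.
* The progressive aligner uses an 8-mer cosine guide tree (average
  linkage), occupancy-weighted profile–profile scoring, affine gaps, and a
  band of ±512 columns around the main diagonal (plus the length
  difference); loci enter at ≤ 15 kb, so the band always covers realistic
  drift for substitution-dominated families.
* Greedy cluster order is length-descending with lexicographic id
  tie-break; an 8-mer cosine pre-filter (similarity < 0.12) skips clearly
  unrelated alignment candidates, mirroring the prefilter stage of k-mer
  clustering tools.
* The scripted analyses run on a 700 kb single-contig species with 36
  implanted copies, and the test suite uses genomes of 12–160 kb; these
  sizes were chosen so the full workflow and suite complete in minutes on
  one CPU while every stage still operates far from its boundary
  conditions.

## Known limitations

* The PSSM engine has no E-value model; thresholds are in bits and were
  calibrated on the synthetic null only.
* Consensus building drops minority-insert columns by construction; an
  insertion present in under half the copies of a family will not appear in
  its consensus.
* The greedy clusterings are order-dependent (deterministically so); they
  are not globally optimal partitions.
* NJ placement is qualitative; no model selection, rate heterogeneity or
  dating is attempted.
* The LTR detector assumes substitution-dominated repeat pairs; long
  indel-rich LTR pairs would require chaining seeds across multiple
  offsets, which is out of scope.
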