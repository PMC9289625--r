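#!/usr/bin/env Rscript
# Step 5 -- full-length element characterization.
#
# Builds the reference giant element (25,510 bp with 6,425 bp LTRs, a
# 2,640 aa polyprotein ORF and a 565 aa 2-ODD ORF), recovers its structure
# with the LTR-pair detector (cap raised to 7 kb: these LTRs exceed the
# stock 3 kb cap), annotates ORFs/PBS/PPT/TIR/dual RNase H, writes a dot
# plot, and reports divergence-capped masking coverage of the synthetic
# genome by the consensus library.

suppressPackageStartupMessages(library(ltrdomains))

lib <- generate_profile_library(seed = 42)
ref_spec <- element_spec("GypRef", total_len = 25510, ltr_len = 6425,
  orf_specs = list(
    list(orf_id = "ORF1", aa_length = 2640,
         cassettes = c("GAG", "PR", "RT_Gypsy", "RNaseH", "RNaseH", "INT",
                       "Chromo")),
    list(orf_id = "ORF2", aa_length = 565, cassettes = c("2-ODD"))),
  divergence = 0, copy_number = 1)
el <- generate_element(ref_spec, seed = 1, library = lib)
set.seed(1)
contig <- paste0(random_dna(5000), el$seq, random_dna(5000))

lp <- find_ltr_pairs(contig, max_ltr_len = 7000)
cat(sprintf("LTR pair: %d bp LTRs, element %d bp, identity %.3f\n",
            lp$ltr_len, lp$end - lp$start, lp$ltr_identity))
ltr5 <- substr(contig, lp$ltr5_start + 1, lp$ltr5_end)
cat(sprintf("TIR length: %d nt\n", detect_tir(ltr5)))

internal <- substr(contig, lp$ltr5_end + 1, lp$ltr3_start)
orfs <- find_orfs(internal, min_aa = 300)
plus <- orfs[orfs$strand == "+", ]
cat(sprintf("plus-strand ORFs: %s aa\n",
            paste(plus$aa_len, collapse = ", ")))
pbs <- detect_pbs(substr(contig, lp$ltr5_end + 1, lp$ltr5_end + 40),
                  lib$trna)
cat(sprintf("PBS: %s (%d nt)\n", pbs$trna, pbs$length))
ppt <- detect_ppt(substr(contig, lp$ltr3_start - 49, lp$ltr3_start))
cat(sprintf("PPT: %d nt at purine fraction %.2f\n", ppt$end - ppt$start,
            ppt$purine_fraction))
cat(sprintf("RNase H copies in ORF1: %d\n",
            detect_dual_rnaseh(plus$aa[1], lib$profiles$RNaseH)))

model <- list(contig = "ref", element = c(lp$start, lp$end),
              ltr5 = c(lp$ltr5_start, lp$ltr5_end),
              ltr3 = c(lp$ltr3_start, lp$ltr3_end),
              tir_len = detect_tir(ltr5),
              orfs_aa = plus$aa_len, pbs = pbs, ppt = ppt,
              rnaseh_copies = detect_dual_rnaseh(plus$aa[1],
                                                 lib$profiles$RNaseH))
jsonlite::write_json(model, "results/element_model.json", auto_unbox = TRUE,
                     digits = NA)

dp <- dotplot(el$seq, word = 15)
write.table(dp, "results/dotplot.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("dot plot: %d word matches (%d reverse-strand)\n", nrow(dp),
            sum(dp$strand == "-")))

# Masking library: full-length elements recovered by the LTR-pair detector,
# clustered to one representative per family. (The RT-locus consensuses are
# the wrong library for masking: their flank-derived columns would smear
# coverage beyond the elements.)
genome <- read_fasta("results/genome_P_synthetica.fa")
lp_all <- find_ltr_pairs(genome[["chr1"]])
cat(sprintf("LTR pairs detected genome-wide: %d\n", nrow(lp_all)))
els <- setNames(substring(genome[["chr1"]], lp_all$start + 1, lp_all$end),
                paste0("el", seq_len(nrow(lp_all))))
# orient every element by its RT hit strand before clustering
rt_profiles <- Filter(function(p) p$family == "RT", lib$profiles)
els <- vapply(els, function(s) {
  h <- scan_domains(s, rt_profiles, threshold = 30)
  if (nrow(h) && h$strand[1] == "-") revcomp(s) else s
}, character(1))
el_df <- data.frame(locus_id = names(els), species_id = "P_synthetica",
                    contig = "chr1", start = lp_all$start, end = lp_all$end,
                    strand = "+", seq = els, stringsAsFactors = FALSE)
cl <- cluster_loci(el_df, min_members = 2)
reps <- vapply(cl, `[[`, character(1), "representative")
cat(sprintf("element families: %d\n", length(reps)))
mask <- mask_coverage(genome, els[reps], max_divergence = 0.20)
cat(sprintf("masking: %d bp, %.1f%% of assembly (%.1f%% excluding gaps)\n",
            mask$masked_bp, 100 * mask$coverage,
            100 * mask$coverage_excl_gaps))
write.table(mask$intervals, "results/mask.bed", sep = "\t", quote = FALSE,
            row.names = FALSE, col.names = FALSE)
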