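#!/usr/bin/env Rscript
# Step 2 -- RT-anchored locus discovery.
#
# Slides the RT profiles over six-frame translations of the genome, merges
# overlapping hits, keeps spans in the 520-840 bp range, clusters RT copies
# per species at 95% identity (50 per cluster), and extends survivors by
# 5 kb per side into candidate loci.

suppressPackageStartupMessages(library(ltrdomains))

lib <- generate_profile_library(seed = 42)
genome <- read_fasta("results/genome_P_synthetica.fa")
rt_profiles <- Filter(function(p) p$family == "RT", lib$profiles)

hits <- scan_rt(genome, rt_profiles, threshold = 30,
                species_id = "P_synthetica")
cat(sprintf("raw merged RT hits: %d\n", nrow(hits)))
hits <- filter_size(hits, 520, 840)
cat(sprintf("hits in 520-840 bp window: %d\n", nrow(hits)))

rt_seqs <- setNames(vapply(seq_len(nrow(hits)), function(i) {
  s <- substr(genome[[hits$contig[i]]], hits$start[i] + 1, hits$end[i])
  if (hits$strand[i] == "-") revcomp(s) else s
}, character(1)), paste0("rt", seq_len(nrow(hits))))
clusters <- cluster_identity(rt_seqs, threshold = 0.95, cap = 50)
cat(sprintf("95%%-identity RT clusters: %d (sizes: %s)\n", length(clusters),
            paste(vapply(clusters, function(cl) length(cl$members),
                         integer(1)), collapse = ", ")))

loci <- extend_loci(hits, genome, flank = 5000)
write_hits_bed(hits, "results/rt_hits.bed")
write_fasta(setNames(loci$seq, loci$locus_id), "results/loci.fa")
cat(sprintf("extended loci written: %d (lengths %d-%d bp)\n", nrow(loci),
            min(nchar(loci$seq)), max(nchar(loci$seq))))
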