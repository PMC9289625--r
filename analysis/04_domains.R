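#!/usr/bin/env Rscript
# Step 4 -- domain annotation and the fixation (n5) report.
#
# Scans every consensus for all profiles, classifies superfamilies from the
# best RT reference hit, collapses redundant profiles, strips the canonical
# LTR-retrotransposon domain families, and tabulates non-canonical domains
# per species, filtered at >= 5 consensus sequences per species.

suppressPackageStartupMessages(library(ltrdomains))

lib <- generate_profile_library(seed = 42)
fa <- read_fasta("results/consensus.fa")
cons <- lapply(names(fa), function(id) {
  structure(list(seq = fa[[id]], species_id = strsplit(id, "|", fixed = TRUE)[[1]][1],
                 consensus_id = id, member_count = NA,
                 member_ids = NULL, match_cols = NULL),
            class = "consensus_record")
})

ann <- annotate_consensuses(cons, lib, min_consensuses = 5)
cat("superfamily calls:\n")
print(ann$superfamilies, row.names = FALSE)
cat("\nnon-canonical domain counts (unfiltered):\n")
print(ann$report$unfiltered)
cat("\nafter the n5 fixation filter:\n")
print(ann$report$filtered)
write_report_tsv(ann$report, "results/domain_report.tsv")
write.table(ann$superfamilies, "results/superfamilies.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

odd <- unique(ann$noncanonical$consensus_id[ann$noncanonical$family == "2-ODD"])
cat(sprintf("\n2-ODD found in %d consensuses; classifications: %s\n",
            length(odd),
            paste(ann$superfamilies$label[
              ann$superfamilies$consensus_id %in% odd], collapse = ", ")))

# cofactor motifs and basic patch on the translated 2-ODD regions
for (id in odd) {
  cs <- cons[[match(id, vapply(cons, `[[`, character(1), "consensus_id"))]]
  aa <- try(extract_domain_region(cs, lib$profiles[["2-ODD"]]), silent = TRUE)
  if (inherits(aa, "try-error")) next
  rec <- check_cofactor_motifs(aa)
  patches <- scan_basic_patch(aa)
  cat(sprintf("  %s: iron core %s, RxxxxxR %s, YNF %s, K/R patches %d\n", id,
              if (is.null(rec$iron_core)) "absent" else "present",
              if (is.null(rec$r_x5_r)) "absent" else "present",
              if (is.null(rec$ynf)) "absent" else "present",
              nrow(patches)))
}
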