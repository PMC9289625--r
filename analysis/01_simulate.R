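#!/usr/bin/env Rscript
# Step 1 -- build the synthetic study system.
#
# One "orchid-like" species (P_synthetica) carries a lineage of Gypsy-type
# elements that gained an extra ORF with a 2-ODD (AlkB-family) domain. The
# lineage has diversified into five subfamilies (~15% from the lineage
# master), each present in six copies at ~2% within-subfamily divergence, so
# discovery yields five distinct 2-ODD-bearing consensus sequences. A plain
# Copia-type family without extra domains serves as negative control, and a
# second species carries a four-copy family that must fall below the
# five-member consensus floor.

suppressPackageStartupMessages(library(ltrdomains))
dir.create("results", showWarnings = FALSE)

lib <- generate_profile_library(seed = 42)

gypsy_spec <- function(fam) element_spec(fam, total_len = 7000,
  ltr_len = 400,
  orf_specs = list(
    list(orf_id = "ORF1", aa_length = 1400,
         cassettes = c("GAG", "PR", "RT_Gypsy", "RNaseH", "RNaseH", "INT")),
    list(orf_id = "ORF2", aa_length = 300, cassettes = c("2-ODD"))),
  divergence = 0.02, copy_number = 6)

lineage <- generate_element(gypsy_spec("GypL"), seed = 101, library = lib)
gyp_specs <- lapply(1:5, function(k) {
  es <- gypsy_spec(paste0("Gyp", k))
  es$master <- derive_subfamily(lineage, rate = 0.15, seed = 200 + k)
  es
})
copia <- element_spec("CopA", total_len = 6000, ltr_len = 350,
  orf_specs = list(list(orf_id = "ORF1", aa_length = 1300,
    cassettes = c("GAG", "PR", "INT", "RT_Copia", "RNaseH"))),
  divergence = 0.02, copy_number = 6)

spec <- genome_spec("P_synthetica", 700000,
                    elements = c(gyp_specs, list(copia)),
                    seed = 31, min_spacing = 12000)
genome <- generate_genome(spec, library = lib)

spec4 <- genome_spec("sp_four", 120000,
                     elements = list({
                       es <- gypsy_spec("Gyp4"); es$copy_number <- 4L; es
                     }),
                     seed = 33, min_spacing = 12000)
genome4 <- generate_genome(spec4, library = lib)

write_fasta(genome$fasta, "results/genome_P_synthetica.fa")
write_truth_gff3(genome, "results/truth_P_synthetica.gff3")
write_genome_spec(spec, "results/spec_P_synthetica.yaml")
write_fasta(genome4$fasta, "results/genome_sp_four.fa")
write_genome_spec(spec4, "results/spec_sp_four.yaml")

cat(sprintf("P_synthetica: %d bp, %d implanted copies (%d families)\n",
            nchar(genome$fasta[["chr1"]]), nrow(genome$truth$copies),
            length(spec$elements)))
cat(sprintf("sp_four:      %d bp, %d implanted copies\n",
            nchar(genome4$fasta[["chr1"]]), nrow(genome4$truth$copies)))
cat("mean realized copy identity:",
    round(mean(genome$truth$copies$identity), 4), "\n")
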