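#!/usr/bin/env Rscript
# Scan the 3'-UTRs for canonical seed sites, normalise miRNA counts to
# TPM, pick the top-10 non-difference and stress-reduced miRNA sets, and
# build the transcript partition (exclusive targets / non-targets /
# single-site strata) under the FPKM filters (> 1 in both samples, mean
# >= 30). Reads results/data/, writes results/tables/.

library(agoshift)

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)

utrs <- read_fasta("results/data/utrs.fasta")
mirnas <- read_fasta("results/data/mirnas.fasta")
counts <- read_mirna_counts("results/data/mirna_counts.tsv")
fpkm <- read_expression_tsv("results/data/fpkm.tsv")

sites <- scan_all_sites(utrs, mirnas)
write_tsv(sites, "results/tables/sites.tsv")
cat("Found", nrow(sites), "seed sites on",
    length(unique(sites$transcript_id)), "of", length(utrs),
    "transcripts:\n")
print(table(sites$site_type))

profiles <- mirna_profiles(counts, sequences = mirnas)
selection <- select_mirnas(profiles, n = 10, min_tpm = 100)
write_tsv(profiles, "results/tables/mirna_profiles.tsv")
cat("\nTop", length(selection$non_difference), "non-difference miRNAs:",
    paste(selection$non_difference, collapse = ", "), "\n")
cat(length(selection$reduced), "stress-reduced miRNAs (log2FC <= -1):",
    paste(selection$reduced, collapse = ", "), "\n")

partition <- build_partition(sites, selection, fpkm,
                             expressed_mirnas = profiles$mirna_id)
write_tsv(partition_table(partition), "results/tables/partition.tsv")
cat("\nAfter expression filtering (", length(partition$universe),
    "transcripts ):", length(partition$exclusive_targets),
    "exclusive targets,", length(partition$non_targets), "non-targets.\n")
cat("Single-site strata:",
    paste(names(partition$single_site_strata),
          lengths(partition$single_site_strata), collapse = ", "), "\n")
write_tsv(data.frame(
  mirna_id = c(selection$non_difference, selection$reduced),
  class = c(rep("non_difference", length(selection$non_difference)),
            rep("reduced", length(selection$reduced)))),
  "results/tables/selection.tsv")
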