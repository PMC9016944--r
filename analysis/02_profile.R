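#!/usr/bin/env Rscript
# Ingest the simulated hmmsearch output: parse the tblout, apply trusted
# bit-score cutoffs and MAG quality tiers, build the MAG x gene presence
# matrix, binarize to participants and write the per-state dot-plot
# statistics. Run after 01_simulate.R.

library(gutsulfur)

res <- run_profile("results/cohort/hits.tblout",
                   "results/cohort/mag_metadata.tsv",
                   "results/profile")
print(res$matrix)
print(res$profiles)

dot <- res$dotplot
top <- dot[order(-dot$prop_participants), ]
message("most prevalent gene-state cells:")
print(head(top[, c("gene", "disease_state", "prop_participants",
                   "mean_mags_carriers")], 5), row.names = FALSE)

# genus rollup: how many genera carry at least one sulfidogenic gene
records <- read_mag_metadata("results/cohort/mag_metadata.tsv")
gs <- genus_gene_summary(res$matrix, records, default_catalog())
message("genera with >= 1 sulfidogenic gene: ", gs$n_sulfidogenic_genera)
write.table(gs$counts, "results/profile/genus_gene_counts.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

acc <- cohort_accounting(records)
write.table(acc, "results/profile/cohort_accounting.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
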