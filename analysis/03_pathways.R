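#!/usr/bin/env Rscript
# Call taurine-reduction pathway completion at MAG, genus and participant
# level on the profiled cohort, list cooperation candidates (participants
# whose pooled MAGs complete a pathway no single MAG completes) and
# tabulate tpa/toa co-occurrence. Run after 02_profile.R.

library(gutsulfur)

mat <- read_presence_table("results/profile/presence_table.tsv")
calls <- run_pathways(mat, "results/cohort/mag_metadata.tsv",
                      "results/pathways")

status_tab <- table(calls$unit_level, calls$status)
print(status_tab)

coop <- calls[!is.na(calls$cooperation_candidate) & calls$cooperation_candidate, ]
message(nrow(coop), " participant-level cooperation candidate calls")
if (nrow(coop) > 0) {
  print(head(coop[, c("unit_id", "pathway", "variant")], 10),
        row.names = FALSE)
}

tab <- cooccurrence_table(mat, "tpa", "toa")
message("tpa/toa co-occurrence across MAGs:")
print(tab)
write.table(as.data.frame(as.table(tab)), "results/pathways/tpa_toa_cooccurrence.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
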