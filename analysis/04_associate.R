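#!/usr/bin/env Rscript
# Association statistics on the profiled cohort: per-gene 2x3 chi-squared
# against disease state with one BH pass, and the Rao score test for a
# stage trend among staged carcinoma participants. The planted mgl
# enrichment from 01_simulate.R should surface at the top of the state
# table. Run after 02_profile.R.

library(gutsulfur)

res_prof <- run_profile("results/cohort/hits.tblout",
                        "results/cohort/mag_metadata.tsv",
                        "results/profile")
# restrict the BH family to the simulated gene panel
panel <- colnames(read_presence_table("results/cohort/presence_table.tsv")$counts)
assoc <- run_associate(res_prof$profiles, "results/associate", genes = panel)

state <- assoc$state[order(assoc$state$p_adj), ]
message("top state associations:")
print(head(state[, c("feature", "statistic", "p_raw", "p_adj", "direction",
                     "signif")], 6), row.names = FALSE)

if (!is.null(assoc$stage)) {
  stage <- assoc$stage[order(assoc$stage$p_adj), ]
  message("top stage-trend associations (carcinoma, stages I-IV):")
  print(head(stage[, c("feature", "statistic", "p_raw", "p_adj")], 4),
        row.names = FALSE)
}

sp <- stage_profile(res_prof$profiles, "mgl")
message("mgl carrier proportion by stage:")
print(sp, row.names = FALSE)
write.table(sp, "results/associate/mgl_stage_profile.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
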