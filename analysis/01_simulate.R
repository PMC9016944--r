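#!/usr/bin/env Rscript
# Simulate a demonstration cohort: 30 participants per disease state, a
# genus-structured gene pool over the taurine/sulfite-reduction genes and a
# planted carcinoma enrichment (odds x3) for mgl. Writes all pipeline input
# files (metadata, presence table, tblout with boundary decoys) under
# results/cohort/.

library(gutsulfur)

catalog <- default_catalog()
genes <- c("tpa", "toa", "xsc", "isfD", "islA", "islB",
           "dsrA", "dsrB", "asrA", "asrB", "asrC", "mgl", "bsh", "sqr")
pool <- random_genus_pool(genes, n_genera = 8, seed = 20, p_range = c(0, 0.15))
effects <- matrix(1, length(genes), 3,
                  dimnames = list(genes, c("healthy", "adenoma", "carcinoma")))
effects["mgl", "carcinoma"] <- 3

config <- cohort_config(
  n_per_state = c(healthy = 30, adenoma = 30, carcinoma = 30),
  genus_pool = pool,
  mags_per_participant = list(family = "nbinom", mu = 5, size = 6),
  effects = effects, copy_lambda = 0.3, seed = 2024)

cohort <- run_simulate(config, "results/cohort", catalog = catalog,
                       decoy_margin = 0.1)
print(cohort)

truth <- planted_effect_truth(config)
write.table(truth, "results/cohort/planted_truth.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("planted mgl carriage (per MAG): healthy ",
        round(truth$prob[truth$gene == "mgl" & truth$disease_state == "healthy"], 3),
        " vs carcinoma ",
        round(truth$prob[truth$gene == "mgl" & truth$disease_state == "carcinoma"], 3))
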