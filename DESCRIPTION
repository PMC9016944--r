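Package: gutsulfur
Title: Sulfur-Metabolism Gene Surveys in Human Gut Metagenome-Assembled Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Catalog-driven detection of microbial sulfur-metabolism genes in
    collections of metagenome-assembled genomes (MAGs) from human gut
    metagenomes, and their association with colorectal disease state. Parses
    hmmsearch tabular output and applies per-profile trusted bit-score
    cutoffs, filters BLAST tabular hits by identity and alignment length,
    applies MAG quality tiers, binarizes gene carriage to the participant
    level, enumerates taurine-reduction pathway variants from a data-driven
    grammar and calls complete, near-complete and first-and-last-only states
    at MAG, genus and participant level, and tests presence against disease
    state (2x3 Pearson chi-squared with Benjamini-Hochberg correction) and
    against cancer stage (binomial-logistic Rao score test). Includes a
    seeded synthetic-cohort generator with genus-structured gene carriage
    and planted state-dependent odds effects for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
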