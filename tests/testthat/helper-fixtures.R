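# Shared fixture builders. Everything is generated in code; no binary data.

write_catalog_file <- function(df, path = tempfile(fileext = ".tsv")) {
  df$trusted_cutoff[is.na(df$trusted_cutoff)] <- ""
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

tiny_catalog_df <- function(symbols = c("dsrA", "dsrB", "mgl"),
                            cutoffs = c(50, 40, 30),
                            classes = NULL,
                            sulfidogenic = NULL) {
  if (is.null(classes)) classes <- rep("inorganic", length(symbols))
  if (is.null(sulfidogenic)) sulfidogenic <- rep(TRUE, length(symbols))
  data.frame(symbol = symbols,
             full_name = paste(symbols, "protein"),
             substrate_class = classes,
             sulfidogenic = sulfidogenic,
             hmm_id = paste0("K", seq_along(symbols) + 10000),
             trusted_cutoff = cutoffs,
             reaction = "r",
             stringsAsFactors = FALSE)
}

tiny_catalog <- function(...) load_catalog(write_catalog_file(tiny_catalog_df(...)))

# participant_profiles built end-to-end from an explicit MAG-level count
# matrix and per-MAG participant/state assignments
profiles_from_counts <- function(counts, participant_id, disease_state,
                                 stage = NULL) {
  records <- data.frame(mag_id = rownames(counts),
                        participant_id = participant_id,
                        disease_state = disease_state,
                        stringsAsFactors = FALSE)
  if (!is.null(stage)) records$stage <- stage
  hits <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
    reps <- rep(colnames(counts), counts[i, ])
    if (length(reps) == 0) return(NULL)
    data.frame(mag_id = rownames(counts)[i], gene_symbol = reps,
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) hits <- data.frame(mag_id = character(0),
                                        gene_symbol = character(0))
  mat <- build_presence_matrix(hits, colnames(counts),
                               mag_ids = rownames(counts))
  binarize_by_participant(mat, records)
}

# one-MAG-per-participant shortcut: presence is a logical participant x gene
# matrix
profiles_from_presence <- function(presence, disease_state, stage = NULL) {
  counts <- (presence >= 1) + 0L
  rownames(counts) <- paste0(rownames(presence), "-M1")
  pr <- profiles_from_counts(counts, rownames(presence), disease_state, stage)
  pr
}

small_null_config <- function(n = 20, genes = paste0("g", 1:6), seed = 1L,
                              n_genera = 5, k = 3, p_range = c(0.05, 0.4)) {
  pool <- random_genus_pool(genes, n_genera = n_genera, seed = seed + 1000,
                            p_range = p_range)
  cohort_config(c(healthy = n, adenoma = n, carcinoma = n), pool,
                mags_per_participant = list(family = "fixed", k = k),
                seed = seed)
}
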