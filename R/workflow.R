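write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

run_manifest <- function(out_dir, seed, inputs, extra = list()) {
  digests <- lapply(inputs, function(p) {
    if (file.exists(p)) unname(tools::md5sum(p)) else NA_character_
  })
  yaml::write_yaml(c(list(
    package_version = as.character(utils::packageVersion("gutsulfur")),
    seed = if (is.null(seed)) "none" else seed,
    input_digests = digests), extra),
    file.path(out_dir, "manifest.yaml"))
}

#' Run the profiling stage: hits to presence to dot-plot statistics
#'
#' Chains ingestion and presence profiling: parses the tblout file,
#' applies trusted-cutoff filtering against the catalog, applies MAG
#' quality tiers to the metadata, builds the MAG-by-gene presence matrix
#' over the surviving MAGs, binarizes to participants and writes the
#' presence table, participant carriage table and per-state dot-plot
#' statistics plus a manifest. Filter counts are reported via
#' \code{message()}.
#'
#' @param tblout Path to hmmsearch tblout output.
#' @param metadata Path to MAG metadata TSV.
#' @param out_dir Output directory.
#' @param catalog A \code{gene_catalog} (default: shipped catalog).
#' @param tiers Quality tiers to keep (default high + medium).
#' @return List: matrix (\code{presence_matrix}), profiles
#'   (\code{participant_profiles}), dotplot (data frame), paths.
#' @export
run_profile <- function(tblout, metadata, out_dir,
                        catalog = default_catalog(),
                        tiers = c("high", "medium")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  parsed <- parse_hmmsearch_tblout(tblout, catalog_profile_map(catalog))
  message("parsed ", nrow(parsed$hits), " hits (",
          nrow(parsed$skipped), " rows skipped: unmapped profiles)")
  hits <- filter_hits_trusted_cutoff(parsed$hits, catalog)
  message("trusted-cutoff filter kept ", nrow(hits), " of ",
          nrow(parsed$hits), " hits")
  records <- read_mag_metadata(metadata)
  kept <- filter_mags_by_quality(records, tiers)
  message("quality filter kept ", nrow(kept), " of ", nrow(records), " MAGs")
  hits <- hits[hits$mag_id %in% kept$mag_id, , drop = FALSE]
  mat <- build_presence_matrix(hits, catalog$symbol, mag_ids = kept$mag_id)
  # full records, not `kept`: participants whose MAGs all failed quality
  # stay in the state denominators (as absences)
  profiles <- binarize_by_participant(mat, records)
  dot <- dotplot_summary(profiles)
  paths <- c(presence = file.path(out_dir, "presence_table.tsv"),
             carriage = file.path(out_dir, "participant_carriage.tsv"),
             dotplot = file.path(out_dir, "dotplot_stats.tsv"))
  write_presence_table(mat, paths[["presence"]])
  carriage <- data.frame(participant_id = profiles$info$participant_id,
                         disease_state = profiles$info$disease_state,
                         n_mags = profiles$info$n_mags,
                         profiles$mags_with_gene,
                         check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(carriage, paths[["carriage"]])
  write_tsv(dot, paths[["dotplot"]])
  run_manifest(out_dir, seed = NULL, inputs = c(tblout, metadata),
               extra = list(n_hits = nrow(hits), n_mags = nrow(kept)))
  list(matrix = mat, profiles = profiles, dotplot = dot, paths = paths)
}

#' Run the pathway stage: completion calls at one or more levels
#'
#' @param matrix A \code{presence_matrix} (e.g. from [run_profile()] or
#'   [read_presence_table()]).
#' @param metadata Path to MAG metadata TSV, or a records data frame.
#' @param out_dir Output directory.
#' @param grammar Path to a pathway-grammar YAML (default: shipped
#'   taurine grammars).
#' @param catalog Catalog used to validate grammar symbols.
#' @param levels Unit levels to call (subset of mag/genus/participant).
#' @return Data frame of pathway calls (all levels bound together);
#'   written to \code{pathway_calls.tsv}.
#' @export
run_pathways <- function(matrix, metadata, out_dir,
                         grammar = NULL, catalog = default_catalog(),
                         levels = c("mag", "genus", "participant")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  defs <- if (is.null(grammar)) load_pathway_grammar(catalog = catalog)
          else load_pathway_grammar(grammar, catalog = catalog)
  records <- if (is.character(metadata)) read_mag_metadata(metadata) else metadata
  calls <- do.call(rbind, lapply(levels, function(lv) {
    call_pathways_at_level(matrix, records, defs, level = lv)
  }))
  write_tsv(calls, file.path(out_dir, "pathway_calls.tsv"))
  run_manifest(out_dir, seed = NULL,
               inputs = if (is.character(metadata)) metadata else character(0),
               extra = list(n_calls = nrow(calls)))
  calls
}

#' Run the association stage: state and stage tests with BH correction
#'
#' @param profiles A \code{participant_profiles} object.
#' @param out_dir Output directory.
#' @param stage_states Disease states entering the stage trend test
#'   (default carcinoma only); set NULL to skip stage testing.
#' @param stage_coding Stage scores for [stage_score_test()].
#' @param genes Feature family to test (default: every gene column); the
#'   BH correction runs within this family.
#' @return List: state (association data frame), stage (stage-test data
#'   frame or NULL); written to \code{state_association.tsv} and
#'   \code{stage_association.tsv}.
#' @export
run_associate <- function(profiles, out_dir, stage_states = "carcinoma",
                          stage_coding = c(I = 1, II = 2, III = 3, IV = 4),
                          genes = colnames(profiles$presence)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  states_present <- unique(profiles$info$disease_state)
  if (length(states_present) < 2) {
    stop("association error: need participants from >= 2 disease states, got: ",
         paste(states_present, collapse = ", "), call. = FALSE)
  }
  state_res <- associate_all(profiles, genes = genes)
  write_tsv(state_res, file.path(out_dir, "state_association.tsv"))
  stage_res <- NULL
  has_staged <- any(!is.na(profiles$info$stage) &
                      profiles$info$disease_state %in% stage_states)
  if (!is.null(stage_states) && has_staged) {
    stage_res <- associate_stage(profiles, genes = genes,
                                 states = stage_states, coding = stage_coding)
    write_tsv(stage_res, file.path(out_dir, "stage_association.tsv"))
  }
  run_manifest(out_dir, seed = NULL, inputs = character(0),
               extra = list(n_features = nrow(state_res)))
  list(state = state_res, stage = stage_res)
}

#' Run the simulation stage: generate and write a synthetic cohort
#'
#' @param config A \code{cohort_config}.
#' @param out_dir Output directory.
#' @param catalog Catalog for the tblout writer (default: shipped).
#' @param decoy_margin Passed to [write_tblout_fixture()].
#' @return The generated \code{synthetic_cohort}; input files and a
#'   manifest (echoing the seed) under \code{out_dir}.
#' @export
run_simulate <- function(config, out_dir, catalog = default_catalog(),
                         decoy_margin = NULL) {
  cohort <- generate_cohort(config)
  write_cohort(cohort, out_dir, catalog, decoy_margin = decoy_margin)
  cohort
}
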