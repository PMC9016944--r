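new_presence_matrix <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)) || nrow(counts) == 0,
            !is.null(colnames(counts)) || ncol(counts) == 0)
  if (any(counts < 0)) stop("presence counts must be >= 0", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(list(counts = counts), class = "presence_matrix")
}

#' Build a MAG-by-gene presence matrix from filtered HMM hits
#'
#' Counts retained hits per MAG per gene. Presence downstream is defined as
#' count >= 1. MAGs listed in \code{mag_ids} appear even with zero hits, so
#' quality-filtered cohorts keep their full denominator.
#'
#' @param hits Data frame with \code{mag_id} and \code{gene_symbol}
#'   (typically the output of [filter_hits_trusted_cutoff()]).
#' @param gene_symbols Character vector declaring the gene columns. A hit
#'   for an undeclared symbol is an error.
#' @param mag_ids Optional character vector declaring the MAG rows;
#'   defaults to the MAGs observed in \code{hits}.
#' @return A \code{presence_matrix}: list with an integer matrix
#'   \code{$counts} (MAGs x genes, dimnames set).
#' @export
build_presence_matrix <- function(hits, gene_symbols, mag_ids = NULL) {
  gene_symbols <- as.character(gene_symbols)
  if (anyDuplicated(gene_symbols)) stop("duplicate gene symbols", call. = FALSE)
  undeclared <- setdiff(unique(hits$gene_symbol), gene_symbols)
  if (length(undeclared) > 0) {
    stop("hits reference undeclared gene symbol(s): ",
         paste(undeclared, collapse = ", "), call. = FALSE)
  }
  if (is.null(mag_ids)) mag_ids <- unique(hits$mag_id)
  mag_ids <- as.character(mag_ids)
  if (anyDuplicated(mag_ids)) stop("duplicate mag ids", call. = FALSE)
  counts <- matrix(0L, nrow = length(mag_ids), ncol = length(gene_symbols),
                   dimnames = list(mag_ids, gene_symbols))
  if (nrow(hits) > 0) {
    orphan <- setdiff(unique(hits$mag_id), mag_ids)
    if (length(orphan) > 0) {
      stop("hits reference undeclared MAG id(s): ",
           paste(orphan, collapse = ", "), call. = FALSE)
    }
    tab <- table(factor(hits$mag_id, levels = mag_ids),
                 factor(hits$gene_symbol, levels = gene_symbols))
    counts[] <- as.integer(tab)
  }
  new_presence_matrix(counts)
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("<presence_matrix> ", nrow(x$counts), " MAGs x ", ncol(x$counts),
      " genes; ", sum(x$counts >= 1L), " present cells\n", sep = "")
  invisible(x)
}

#' Binarize gene carriage to the participant level
#'
#' A participant carries a gene if at least one of their MAGs has at least
#' one retained hit for it. \code{mags_with_gene} counts carrying MAGs
#' (not hit copies). Participants whose MAGs were all removed by quality
#' filtering still appear (with \code{n_mags = 0} and all-absent genes)
#' when present in \code{records}, keeping state denominators honest.
#'
#' @param matrix A \code{presence_matrix}.
#' @param records MAG metadata mapping every matrix MAG to exactly one
#'   participant (columns mag_id, participant_id, disease_state, optional
#'   stage).
#' @return An object of class \code{participant_profiles}: list with
#'   \code{info} (data frame: participant_id, disease_state, stage,
#'   n_mags), logical matrix \code{presence} and integer matrix
#'   \code{mags_with_gene} (participants x genes).
#' @export
binarize_by_participant <- function(matrix, records) {
  counts <- matrix$counts
  idx <- match(rownames(counts), records$mag_id)
  if (anyNA(idx)) {
    stop("MAG(s) without metadata: ",
         paste(rownames(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  participants <- unique(records$participant_id)
  pidx <- match(records$participant_id[idx], participants)
  carrier <- counts >= 1L
  # participants in records with zero MAGs in the matrix keep all-zero rows
  mags_with_gene <- matrix(0L, nrow = length(participants), ncol = ncol(counts),
                           dimnames = list(participants, colnames(counts)))
  if (nrow(counts) > 0) {
    rs <- rowsum(carrier + 0L, group = pidx)
    mags_with_gene[as.integer(rownames(rs)), ] <- rs
  }
  n_mags <- as.integer(table(factor(records$participant_id[idx],
                                    levels = participants)))
  first <- match(participants, records$participant_id)
  info <- data.frame(
    participant_id = participants,
    disease_state = records$disease_state[first],
    stage = if ("stage" %in% names(records)) records$stage[first] else NA_character_,
    n_mags = n_mags,
    stringsAsFactors = FALSE)
  state_per_p <- tapply(records$disease_state, records$participant_id, function(s) length(unique(s)))
  if (any(state_per_p > 1)) {
    stop("participant(s) with conflicting disease states in metadata",
         call. = FALSE)
  }
  storage.mode(mags_with_gene) <- "integer"
  structure(list(info = info,
                 presence = mags_with_gene >= 1L,
                 mags_with_gene = mags_with_gene),
            class = "participant_profiles")
}

#' @export
print.participant_profiles <- function(x, ...) {
  cat("<participant_profiles> ", nrow(x$info), " participants x ",
      ncol(x$presence), " genes\n", sep = "")
  print(table(x$info$disease_state))
  invisible(x)
}

#' Per-gene, per-state carriage summaries (dot-plot statistics)
#'
#' For each gene and disease state: the proportion of that state's
#' participants carrying the gene (carriers over the state's full
#' denominator) and, among carriers only, the mean number of their MAGs
#' carrying it (NA when the state has no carriers).
#'
#' @param profiles A \code{participant_profiles} object.
#' @param genes Gene symbols to summarize (default: all).
#' @return Data frame: gene, disease_state, n_state, n_carriers,
#'   prop_participants, mean_mags_carriers.
#' @export
dotplot_summary <- function(profiles, genes = colnames(profiles$presence)) {
  info <- profiles$info
  states <- DISEASE_STATES[DISEASE_STATES %in% info$disease_state]
  out <- list()
  for (g in genes) {
    pres <- profiles$presence[, g]
    mwg <- profiles$mags_with_gene[, g]
    for (s in states) {
      in_state <- info$disease_state == s
      carriers <- in_state & pres
      out[[length(out) + 1]] <- data.frame(
        gene = g, disease_state = s,
        n_state = sum(in_state), n_carriers = sum(carriers),
        prop_participants = sum(carriers) / sum(in_state),
        mean_mags_carriers = if (any(carriers)) mean(mwg[carriers]) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Genus-level gene carriage summary
#'
#' Counts, per genus and gene, the MAGs of that genus carrying the gene,
#' and rolls up the number of distinct genera harboring at least one
#' sulfidogenic gene. MAGs without a genus label fall into an
#' \code{"unclassified"} bucket.
#'
#' @param matrix A \code{presence_matrix}.
#' @param records MAG metadata with \code{genus_label}.
#' @param catalog A \code{gene_catalog} (defines which genes are
#'   sulfidogenic).
#' @return List with \code{counts} (long data frame: genus, gene,
#'   n_mags_with_gene) and \code{n_sulfidogenic_genera} (integer).
#' @export
genus_gene_summary <- function(matrix, records, catalog) {
  counts <- matrix$counts
  idx <- match(rownames(counts), records$mag_id)
  if (anyNA(idx)) {
    stop("MAG(s) without metadata: ",
         paste(rownames(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  genus <- if ("genus_label" %in% names(records)) records$genus_label[idx] else rep(NA_character_, length(idx))
  genus[is.na(genus) | genus == ""] <- "unclassified"
  genera <- sort(unique(genus))
  carrier <- counts >= 1L
  per_genus <- rowsum(carrier + 0L, group = factor(genus, levels = genera))
  long <- data.frame(
    genus = rep(genera, times = ncol(per_genus)),
    gene = rep(colnames(per_genus), each = length(genera)),
    n_mags_with_gene = as.integer(per_genus),
    stringsAsFactors = FALSE)
  sulf <- intersect(sulfidogenic_symbols(catalog), colnames(per_genus))
  n_sulf_genera <- if (length(sulf) == 0) 0L else
    sum(rowSums(per_genus[, sulf, drop = FALSE]) > 0)
  list(counts = long, n_sulfidogenic_genera = as.integer(n_sulf_genera))
}

#' Tabulate participants and MAGs per study and disease state
#'
#' Aggregates MAG records into the study-by-state accounting table
#' (number of distinct participants and number of MAGs per cell).
#'
#' @param records MAG metadata data frame (may be empty).
#' @return Data frame: study, disease_state, n_participants, n_mags.
#' @seealso [cohort_totals()], [read_cohort_overview()]
#' @export
cohort_accounting <- function(records) {
  if (nrow(records) == 0) {
    return(data.frame(study = character(0), disease_state = character(0),
                      n_participants = integer(0), n_mags = integer(0),
                      stringsAsFactors = FALSE))
  }
  study <- if ("study" %in% names(records)) records$study else "all"
  key <- paste(study, records$disease_state, sep = "\r")
  agg <- lapply(split(seq_len(nrow(records)), key), function(i) {
    data.frame(study = study[i[1]], disease_state = records$disease_state[i[1]],
               n_participants = length(unique(records$participant_id[i])),
               n_mags = length(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$study, match(out$disease_state, DISEASE_STATES)), ]
  rownames(out) <- NULL
  out
}

#' Grand totals of a cohort accounting table
#'
#' @param overview Data frame with disease_state, n_participants, n_mags
#'   (e.g. from [cohort_accounting()] or [read_cohort_overview()]).
#' @return List with \code{total_mags}, \code{total_participants} and
#'   \code{by_state} (named vectors of participant and MAG totals per
#'   state).
#' @export
cohort_totals <- function(overview) {
  flat <- function(x) stats::setNames(as.vector(x), names(x))
  by_state_p <- flat(tapply(overview$n_participants, overview$disease_state, sum))
  by_state_m <- flat(tapply(overview$n_mags, overview$disease_state, sum))
  ord <- DISEASE_STATES[DISEASE_STATES %in% names(by_state_p)]
  list(total_mags = sum(overview$n_mags),
       total_participants = sum(overview$n_participants),
       by_state = list(participants = by_state_p[ord], mags = by_state_m[ord]))
}

#' Read a published cohort-overview table
#'
#' Loads a study-by-state summary TSV (columns study, disease_state,
#' n_participants, n_mags). The shipped default transcribes the five
#' public colorectal-cancer stool cohorts used by the survey.
#'
#' @param path TSV path; default is the shipped table.
#' @return Data frame: study, disease_state, n_participants, n_mags.
#' @export
read_cohort_overview <- function(path = system.file("extdata", "cohort_overview.tsv",
                                                    package = "gutsulfur",
                                                    mustWork = TRUE)) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("study", "disease_state", "n_participants", "n_mags")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("cohort overview format error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df
}
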