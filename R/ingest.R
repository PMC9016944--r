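DISEASE_STATES <- c("healthy", "adenoma", "carcinoma")

# synonym map applied by read_mag_metadata(); keys are lowercased tokens
DISEASE_STATE_SYNONYMS <- c(
  healthy = "healthy", control = "healthy", "control/healthy" = "healthy",
  adenoma = "adenoma",
  carcinoma = "carcinoma", crc = "carcinoma", cancer = "carcinoma"
)

#' Parse hmmsearch per-target tabular output (tblout)
#'
#' Reads the HMMER3 \code{--tblout} dialect: whitespace-aligned columns,
#' \code{#} comment lines, with target name, query (profile) name and the
#' full-sequence E-value and bit score in their standard positions
#' (columns 1, 3, 5, 6). Rows whose profile id is absent from
#' \code{profile_to_symbol} are not an error: they are collected into the
#' \code{skipped} report.
#'
#' @param path tblout file path.
#' @param profile_to_symbol Named character vector mapping profile ids
#'   (query names) to catalog gene symbols; see [catalog_profile_map()].
#' @param mag_id_pattern Regex stripped from the target (protein) id to
#'   recover the MAG id. Default removes a Prodigal-style trailing ORF
#'   number (\code{"_12"}).
#' @return List with \code{hits} (data frame: mag_id, protein_id,
#'   profile_id, gene_symbol, full_seq_score, full_seq_evalue) and
#'   \code{skipped} (data frame: line, protein_id, profile_id).
#' @export
parse_hmmsearch_tblout <- function(path, profile_to_symbol,
                                   mag_id_pattern = "_[0-9]+$") {
  if (!file.exists(path)) stop("cannot read tblout file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  hits <- list()
  skipped <- list()
  for (i in which(keep)) {
    fields <- strsplit(trimws(lines[[i]]), "\\s+")[[1]]
    if (length(fields) < 18) {
      stop("tblout parse error at line ", i, ": expected >= 18 columns, got ",
           length(fields), call. = FALSE)
    }
    protein_id <- fields[[1]]
    profile_id <- fields[[3]]
    symbol <- unname(profile_to_symbol[profile_id])
    if (is.null(symbol) || is.na(symbol)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(line = i, protein_id = protein_id, profile_id = profile_id,
                   stringsAsFactors = FALSE)
      next
    }
    score <- as.numeric(fields[[6]])
    evalue <- as.numeric(fields[[5]])
    if (is.na(score) || is.na(evalue)) {
      stop("tblout parse error at line ", i,
           ": non-numeric E-value/score field", call. = FALSE)
    }
    hits[[length(hits) + 1]] <- data.frame(
      mag_id = sub(mag_id_pattern, "", protein_id),
      protein_id = protein_id, profile_id = profile_id, gene_symbol = symbol,
      full_seq_score = score, full_seq_evalue = evalue,
      stringsAsFactors = FALSE)
  }
  empty_hits <- data.frame(mag_id = character(0), protein_id = character(0),
                           profile_id = character(0), gene_symbol = character(0),
                           full_seq_score = numeric(0),
                           full_seq_evalue = numeric(0),
                           stringsAsFactors = FALSE)
  empty_skip <- data.frame(line = integer(0), protein_id = character(0),
                           profile_id = character(0), stringsAsFactors = FALSE)
  list(
    hits = if (length(hits)) do.call(rbind, hits) else empty_hits,
    skipped = if (length(skipped)) do.call(rbind, skipped) else empty_skip
  )
}

#' Filter HMM hits by per-gene trusted bit-score cutoffs
#'
#' Retains hits whose full-sequence bit score is at least the trusted
#' cutoff of the hit's gene (inclusive at equality, matching HMMER's own
#' trusted-cutoff convention). Hits to genes without a curated cutoff are
#' retained and flagged in the \code{no_cutoff} column so downstream users
#' can treat them separately. Input order is preserved.
#'
#' @param hits Data frame as returned in \code{$hits} by
#'   [parse_hmmsearch_tblout()].
#' @param catalog A \code{gene_catalog} resolving every \code{gene_symbol}.
#' @return The retained rows of \code{hits}, with a logical
#'   \code{no_cutoff} column appended.
#' @export
filter_hits_trusted_cutoff <- function(hits, catalog) {
  if (nrow(hits) == 0) {
    hits$no_cutoff <- logical(0)
    return(hits)
  }
  rows <- catalog_lookup(catalog, hits$gene_symbol)
  cutoff <- rows$trusted_cutoff
  no_cutoff <- is.na(cutoff)
  keep <- no_cutoff | hits$full_seq_score >= cutoff
  out <- hits[keep, , drop = FALSE]
  out$no_cutoff <- no_cutoff[keep]
  rownames(out) <- NULL
  out
}

#' Parse BLAST tabular output (outfmt 6)
#'
#' Reads the 12 standard columns of BLAST \code{-outfmt 6}.
#'
#' @param path File path.
#' @return Data frame with columns query_id, subject_id, pct_identity,
#'   align_length, mismatches, gap_opens, q_start, q_end, s_start, s_end,
#'   evalue, bitscore.
#' @export
parse_blast_outfmt6 <- function(path) {
  if (!file.exists(path)) stop("cannot read BLAST file: ", path, call. = FALSE)
  cols <- c("query_id", "subject_id", "pct_identity", "align_length",
            "mismatches", "gap_opens", "q_start", "q_end", "s_start", "s_end",
            "evalue", "bitscore")
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 12) {
    stop("BLAST outfmt-6 parse error: expected 12 columns, got ", ncol(df),
         call. = FALSE)
  }
  df <- df[, 1:12]
  names(df) <- cols
  df
}

#' Filter BLAST hits by identity and alignment length
#'
#' Retains alignments with percent identity strictly greater than
#' \code{min_identity} and alignment length of at least
#' \code{min_align_len} amino acids (the survey convention: "> 60\%
#' identity" is strict, the 40-aa coverage floor is inclusive).
#'
#' @param hits Data frame with \code{pct_identity} and \code{align_length}.
#' @param min_identity Percent identity threshold (default 60, exclusive).
#' @param min_align_len Alignment length floor in aa (default 40, inclusive).
#' @return The retained rows, order preserved.
#' @export
filter_blast_hits <- function(hits, min_identity = 60, min_align_len = 40) {
  keep <- hits$pct_identity > min_identity & hits$align_length >= min_align_len
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter MAG records by assembly quality tier
#'
#' Keeps a MAG if it satisfies any requested tier: \code{"high"} means
#' completeness > 90, contamination < 5 and strain heterogeneity < 0.5
#' (unreachable when strain heterogeneity is missing); \code{"medium"}
#' means completeness > 50 and contamination < 5. All inequalities are
#' strict.
#'
#' @param records MAG metadata data frame (see [read_mag_metadata()]).
#' @param tiers Character subset of \code{c("high", "medium")}.
#' @return The retained rows, order preserved.
#' @export
filter_mags_by_quality <- function(records, tiers = c("high", "medium")) {
  tiers <- match.arg(tiers, c("high", "medium"), several.ok = TRUE)
  het <- records$strain_heterogeneity
  if (is.null(het)) het <- rep(NA_real_, nrow(records))
  high <- records$completeness > 90 & records$contamination < 5 &
    !is.na(het) & het < 0.5
  medium <- records$completeness > 50 & records$contamination < 5
  keep <- rep(FALSE, nrow(records))
  if ("high" %in% tiers) keep <- keep | high
  if ("medium" %in% tiers) keep <- keep | medium
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read MAG metadata
#'
#' Reads a tab-separated MAG metadata table with columns \code{mag_id},
#' \code{participant_id}, \code{study}, \code{disease_state} and
#' optionally \code{stage}, \code{genus_label}, \code{completeness},
#' \code{contamination}, \code{strain_heterogeneity}. Disease-state
#' synonyms are normalized (\code{control} to healthy, \code{CRC} to
#' carcinoma).
#'
#' @param path TSV file path.
#' @return Validated data frame of MAG records.
#' @export
read_mag_metadata <- function(path) {
  if (!file.exists(path)) stop("cannot read metadata file: ", path, call. = FALSE)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_mag_records(df)
}

validate_mag_records <- function(df) {
  required <- c("mag_id", "participant_id", "disease_state")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("metadata validation error: missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$participant_id) | df$participant_id == "")) {
    stop("metadata validation error: missing participant_id", call. = FALSE)
  }
  dup <- unique(df$mag_id[duplicated(df$mag_id)])
  if (length(dup) > 0) {
    stop("metadata validation error: duplicate mag_id(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  state <- unname(DISEASE_STATE_SYNONYMS[tolower(trimws(df$disease_state))])
  if (anyNA(state)) {
    bad <- unique(df$disease_state[is.na(state)])
    stop("metadata validation error: unknown disease state value(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df$disease_state <- state
  for (col in c("completeness", "contamination")) {
    if (col %in% names(df)) {
      v <- df[[col]]
      if (any(!is.na(v) & (v < 0 | v > 100))) {
        stop("metadata validation error: ", col, " outside [0, 100]",
             call. = FALSE)
      }
    }
  }
  if ("stage" %in% names(df)) {
    bad <- !is.na(df$stage) & df$stage != "" &
      !df$stage %in% c("I", "II", "III", "IV", "unstaged")
    if (any(bad)) {
      stop("metadata validation error: unknown stage value(s): ",
           paste(unique(df$stage[bad]), collapse = ", "), call. = FALSE)
    }
    df$stage[df$stage == ""] <- NA_character_
  }
  df
}

#' Write MAG metadata
#' @param records MAG metadata data frame.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_mag_metadata <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Map a TNM classification to a colorectal cancer stage
#'
#' Applies an editable wildcard lookup table (first matching row wins;
#' \code{*} matches any token) encoding a simplified colorectal staging
#' rule: any M1 is stage IV, nodal involvement without distant metastasis
#' is stage III, and node-negative tumors split I (T1/T2) versus II
#' (T3/T4). Unmatched triples return \code{"unstaged"}, never a guess.
#'
#' @param t,n,m Character vectors of T, N, M tokens (recycled to a common
#'   length).
#' @param lookup Lookup table (columns t, n, m, stage); default is the
#'   shipped table.
#' @return Character vector of stages in \code{c("I","II","III","IV",
#'   "unstaged")}.
#' @export
tnm_to_stage <- function(t, n, m, lookup = default_tnm_table()) {
  len <- max(length(t), length(n), length(m))
  t <- rep_len(as.character(t), len)
  n <- rep_len(as.character(n), len)
  m <- rep_len(as.character(m), len)
  if (any(is.na(t) | is.na(n) | is.na(m))) {
    stop("tnm validation error: NA token", call. = FALSE)
  }
  vapply(seq_len(len), function(i) {
    hit <- (lookup$t == "*" | lookup$t == t[i]) &
           (lookup$n == "*" | lookup$n == n[i]) &
           (lookup$m == "*" | lookup$m == m[i])
    if (any(hit)) lookup$stage[which(hit)[1]] else "unstaged"
  }, character(1))
}

#' Shipped TNM-to-stage lookup table
#' @return Data frame with columns t, n, m, stage.
#' @export
default_tnm_table <- function() {
  utils::read.delim(system.file("extdata", "tnm_stage_map.tsv",
                                package = "gutsulfur", mustWork = TRUE),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Read a wide gene-presence table
#'
#' Reads the wide survey dialect: first column MAG id, remaining columns
#' gene symbols, and each cell either the column's own gene symbol
#' (present) or \code{"N/A"} (absent). Returns a binary
#' \code{presence_matrix} (counts 0/1).
#'
#' @param path TSV file path.
#' @return A \code{presence_matrix}; see [build_presence_matrix()].
#' @export
read_presence_table <- function(path) {
  if (!file.exists(path)) stop("cannot read presence table: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                          colClasses = "character", na.strings = NULL,
                          stringsAsFactors = FALSE)
  mag_ids <- df[[1]]
  genes <- names(df)[-1]
  counts <- matrix(0L, nrow = nrow(df), ncol = length(genes),
                   dimnames = list(mag_ids, genes))
  for (j in seq_along(genes)) {
    cell <- df[[j + 1]]
    bad <- !(cell == genes[j] | cell == "N/A")
    if (any(bad)) {
      i <- which(bad)[1]
      stop("presence-table format error at row ", i, ", column '", genes[j],
           "': cell '", cell[i], "' is neither '", genes[j], "' nor 'N/A'",
           call. = FALSE)
    }
    counts[, j] <- as.integer(cell == genes[j])
  }
  new_presence_matrix(counts)
}

#' Write a presence matrix in the wide survey dialect
#'
#' Cells carry the gene symbol where the MAG has at least one copy and
#' \code{"N/A"} otherwise, so \code{read_presence_table(write_presence_table(m))}
#' equals the binarization of \code{m}.
#'
#' @param matrix A \code{presence_matrix}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_presence_table <- function(matrix, path) {
  counts <- matrix$counts
  cells <- vapply(seq_len(ncol(counts)), function(j) {
    ifelse(counts[, j] >= 1L, colnames(counts)[j], "N/A")
  }, character(nrow(counts)))
  if (nrow(counts) == 1L) cells <- t(cells)  # vapply drops to vector
  out <- data.frame(mag_id = rownames(counts), cells,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out) <- c("mag_id", colnames(counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
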