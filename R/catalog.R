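#' @keywords internal
"_PACKAGE"

SUBSTRATE_CLASSES <- c("inorganic", "organic_cys_met", "organic_taurine", "accessory")

CATALOG_COLUMNS <- c("symbol", "full_name", "substrate_class", "sulfidogenic",
                     "hmm_id", "trusted_cutoff", "reaction")

#' Load a sulfur-gene catalog
#'
#' Reads a tab-separated catalog of gene definitions. Required columns:
#' \code{symbol}, \code{full_name}, \code{substrate_class},
#' \code{sulfidogenic}, \code{hmm_id}, \code{trusted_cutoff},
#' \code{reaction}. Lines starting with \code{#} are comments. An empty
#' \code{trusted_cutoff} marks a profile without a curated bit-score
#' threshold; hits to such profiles are retained but flagged by
#' [filter_hits_trusted_cutoff()].
#'
#' @param path Path to a UTF-8 TSV catalog file.
#' @return A data frame of class \code{gene_catalog}, one row per gene,
#'   with a \code{version} attribute.
#' @seealso [default_catalog()], [classify_substrate()], [write_catalog()]
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) {
    stop("catalog file not found: ", path, call. = FALSE)
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character", na.strings = NULL)
  missing_cols <- setdiff(CATALOG_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("catalog format error: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- df[CATALOG_COLUMNS]
  df$sulfidogenic <- as.logical(df$sulfidogenic)
  df$trusted_cutoff <- suppressWarnings(
    ifelse(df$trusted_cutoff == "", NA_real_, as.numeric(df$trusted_cutoff)))
  new_gene_catalog(df, version = basename(path))
}

new_gene_catalog <- function(df, version = "unversioned") {
  validate_catalog(df)
  attr(df, "version") <- version
  class(df) <- c("gene_catalog", "data.frame")
  df
}

validate_catalog <- function(df) {
  if (nrow(df) == 0) stop("catalog is empty", call. = FALSE)
  dup <- unique(df$symbol[duplicated(df$symbol)])
  if (length(dup) > 0) {
    stop("catalog validation error: duplicate symbol(s): ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  bad_class <- unique(df$substrate_class[!df$substrate_class %in% SUBSTRATE_CLASSES])
  if (length(bad_class) > 0) {
    stop("catalog validation error: unknown substrate_class value(s): ",
         paste(bad_class, collapse = ", "),
         " (allowed: ", paste(SUBSTRATE_CLASSES, collapse = ", "), ")",
         call. = FALSE)
  }
  cutoff <- df$trusted_cutoff
  bad_cut <- !is.na(cutoff) & (!is.finite(cutoff) | cutoff < 0)
  if (any(bad_cut)) {
    stop("catalog validation error: trusted_cutoff must be finite and >= 0 for: ",
         paste(df$symbol[bad_cut], collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$sulfidogenic))) {
    stop("catalog validation error: sulfidogenic must be TRUE/FALSE", call. = FALSE)
  }
  invisible(df)
}

#' Shipped default sulfur-gene catalog
#'
#' Loads the package's built-in 79-entry catalog of sulfur-metabolism genes
#' (dissimilatory and anaerobic sulfite reduction, taurine reduction,
#' cysteine/methionine degradation, transport and sulfur-relay accessories).
#' Entries not named in the survey literature are synthetic placeholders
#' standing in for the full published gene table; substitute your own file
#' via [load_catalog()] when the complete table is available.
#'
#' @return A \code{gene_catalog} with 79 rows.
#' @export
default_catalog <- function() {
  load_catalog(system.file("extdata", "sulfur_gene_catalog_synthetic.tsv",
                           package = "gutsulfur", mustWork = TRUE))
}

#' Write a catalog back to TSV
#'
#' Inverse of [load_catalog()]: \code{load_catalog(write_catalog(cat, f))}
#' reproduces \code{cat} exactly (modulo the \code{version} attribute).
#'
#' @param catalog A \code{gene_catalog}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "gene_catalog"))
  df <- as.data.frame(catalog)
  df$trusted_cutoff <- ifelse(is.na(df$trusted_cutoff), "",
                              format(df$trusted_cutoff, trim = TRUE, scientific = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Resolve symbols against a catalog
#'
#' @param catalog A \code{gene_catalog}.
#' @param symbols Character vector of gene symbols.
#' @return The matching catalog rows, in the order of \code{symbols}.
#'   Errors if any symbol does not resolve.
#' @export
catalog_lookup <- function(catalog, symbols) {
  idx <- match(symbols, catalog$symbol)
  if (anyNA(idx)) {
    stop("symbol lookup error: not in catalog: ",
         paste(unique(symbols[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  catalog[idx, , drop = FALSE]
}

#' Partition gene symbols by substrate class
#'
#' Splits a set of gene symbols into the four substrate classes used for
#' sulfur metabolism: genes acting on inorganic sulfate/sulfite, on the
#' sulfur amino acids cysteine/methionine, on taurine and other organic
#' sulfonates, and accessory genes. The result is a true partition: every
#' input symbol appears in exactly one class.
#'
#' @param catalog A \code{gene_catalog}.
#' @param symbols Character vector (possibly empty) of symbols to classify.
#' @return Named list with one character vector per substrate class (all
#'   four classes always present, possibly empty).
#' @export
classify_substrate <- function(catalog, symbols) {
  symbols <- unique(as.character(symbols))
  out <- stats::setNames(
    lapply(SUBSTRATE_CLASSES, function(cl) character(0)), SUBSTRATE_CLASSES)
  if (length(symbols) == 0) return(out)
  rows <- catalog_lookup(catalog, symbols)
  for (cl in SUBSTRATE_CLASSES) {
    out[[cl]] <- symbols[rows$substrate_class == cl]
  }
  out
}

#' Sulfidogenic symbols of a catalog
#'
#' @param catalog A \code{gene_catalog}.
#' @return Character vector of symbols whose reaction directly yields
#'   hydrogen sulfide.
#' @export
sulfidogenic_symbols <- function(catalog) {
  catalog$symbol[catalog$sulfidogenic]
}

#' Profile-to-symbol mapping of a catalog
#'
#' @param catalog A \code{gene_catalog}.
#' @return Named character vector mapping HMM profile ids to gene symbols,
#'   for use with [parse_hmmsearch_tblout()].
#' @export
catalog_profile_map <- function(catalog) {
  stats::setNames(catalog$symbol, catalog$hmm_id)
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("<gene_catalog> ", nrow(x), " genes (version ", attr(x, "version"), ")\n",
      sep = "")
  tab <- table(factor(x$substrate_class, levels = SUBSTRATE_CLASSES))
  cat("  by substrate class: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  cat("  sulfidogenic: ", sum(x$sulfidogenic), "\n", sep = "")
  invisible(x)
}
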