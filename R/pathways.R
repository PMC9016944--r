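PATHWAY_STATUSES <- c("absent", "first_and_last_only", "near_complete", "complete")

#' Load pathway grammars from a YAML config
#'
#' A grammar is an ordered list of steps; each step lists alternative
#' requirements and each requirement is an AND-set of gene symbols (so a
#' two-subunit enzyme like dsrAB is the AND-set \code{c("dsrA","dsrB")}).
#' The number of concrete pathway variants is the product of per-step
#' alternative counts. The shipped default encodes the taurine-reduction
#' families: a 3-step grammar (deamination via tpa or toa, sulfoacetaldehyde
#' cleavage via xsc, terminal sulfite reduction via dsrAB or asrABC) and a
#' 4-step grammar (deamination, reduction to isethionate via isfD, cleavage
#' via islAB, terminal reduction) - 4 variants each.
#'
#' @param path YAML file path; default is the shipped grammar.
#' @param catalog Optional \code{gene_catalog}; when given, every grammar
#'   symbol must resolve in it.
#' @return Named list of \code{pathway_definition} objects (name, steps,
#'   excluded_genes).
#' @export
load_pathway_grammar <- function(path = system.file("extdata", "taurine_pathways.yaml",
                                                    package = "gutsulfur",
                                                    mustWork = TRUE),
                                 catalog = NULL) {
  if (!file.exists(path)) {
    stop("cannot read grammar file: ", path, call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$pathways)) {
    stop("grammar validation error: no 'pathways' key in ", path, call. = FALSE)
  }
  defs <- lapply(cfg$pathways, function(p) {
    steps <- lapply(p$steps, function(s) {
      alts <- lapply(s$alternatives, as.character)
      new_pathway_step(s$label, alts)
    })
    new_pathway_definition(p$name, steps,
                           excluded_genes = as.character(unlist(p$excluded_genes)))
  })
  names(defs) <- vapply(defs, function(d) d$name, character(1))
  if (!is.null(catalog)) {
    for (d in defs) {
      syms <- unique(unlist(lapply(d$steps, function(s) unlist(s$alternatives))))
      catalog_lookup(catalog, syms)  # errors on unresolved symbols
    }
  }
  defs
}

new_pathway_step <- function(label, alternatives) {
  if (length(alternatives) < 1) {
    stop("grammar validation error: step '", label,
         "' has zero alternatives", call. = FALSE)
  }
  if (any(vapply(alternatives, length, integer(1)) == 0)) {
    stop("grammar validation error: empty AND-set in step '", label, "'",
         call. = FALSE)
  }
  list(label = label, alternatives = alternatives)
}

new_pathway_definition <- function(name, steps, excluded_genes = character(0)) {
  if (length(steps) < 2) {
    stop("grammar validation error: pathway '", name,
         "' needs at least 2 steps", call. = FALSE)
  }
  structure(list(name = name, steps = steps, excluded_genes = excluded_genes),
            class = "pathway_definition")
}

#' @export
print.pathway_definition <- function(x, ...) {
  cat("<pathway_definition> ", x$name, ": ", length(x$steps), " steps, ",
      prod(vapply(x$steps, function(s) length(s$alternatives), integer(1))),
      " variants\n", sep = "")
  invisible(x)
}

requirement_id <- function(and_set) paste(and_set, collapse = "+")

#' Enumerate the concrete variants of a pathway definition
#'
#' Takes the Cartesian product over steps of their alternative
#' requirements in deterministic order: alternatives in grammar
#' declaration order, with later steps varying fastest. For the shipped
#' 3-step grammar this yields tpa+xsc+dsrAB, tpa+xsc+asrABC,
#' toa+xsc+dsrAB, toa+xsc+asrABC.
#'
#' @param definition A \code{pathway_definition}.
#' @return List of variants; each variant is a list with one AND-set
#'   (character vector) per step, named by step label.
#' @export
enumerate_variants <- function(definition) {
  step_alts <- lapply(definition$steps, function(s) s$alternatives)
  labels <- vapply(definition$steps, function(s) s$label, character(1))
  idx_grid <- expand.grid(rev(lapply(step_alts, seq_along)))[, rev(seq_along(step_alts)), drop = FALSE]
  lapply(seq_len(nrow(idx_grid)), function(r) {
    v <- lapply(seq_along(step_alts), function(k) step_alts[[k]][[idx_grid[r, k]]])
    names(v) <- labels
    v
  })
}

#' Call a pathway's completion state for one gene set
#'
#' A step is satisfied when some alternative's AND-set is a subset of the
#' gene set. Status is \code{complete} (all steps), otherwise
#' \code{first_and_last_only} (first and last satisfied, at least one
#' interior step missing), otherwise \code{near_complete} (exactly one
#' step missing), otherwise \code{absent}. first_and_last_only takes
#' precedence over near_complete whenever both apply, since those units
#' are the metabolic-cooperation / novel-enzyme discovery candidates the
#' survey reports separately. The reported variant maximizes the number of
#' fully satisfied steps (ties broken by enumeration order).
#'
#' @param gene_set Character vector of gene symbols present in the unit.
#' @param definition A \code{pathway_definition}.
#' @return List of class \code{pathway_call}: pathway, status,
#'   missing_steps (labels), satisfied (logical per step), variant,
#'   terminal (the requirement id satisfied at the final step, NA if
#'   unsatisfied).
#' @export
call_pathway <- function(gene_set, definition) {
  gene_set <- unique(as.character(gene_set))
  steps <- definition$steps
  n <- length(steps)
  satisfied <- vapply(steps, function(s) {
    any(vapply(s$alternatives, function(req) all(req %in% gene_set), logical(1)))
  }, logical(1))
  labels <- vapply(steps, function(s) s$label, character(1))
  missing_steps <- labels[!satisfied]
  status <- if (all(satisfied)) {
    "complete"
  } else if (satisfied[1] && satisfied[n] && any(!satisfied[-c(1, n)])) {
    "first_and_last_only"
  } else if (sum(!satisfied) == 1) {
    "near_complete"
  } else {
    "absent"
  }
  variants <- enumerate_variants(definition)
  sat_count <- vapply(variants, function(v) {
    sum(vapply(v, function(req) all(req %in% gene_set), logical(1)))
  }, integer(1))
  variant <- variants[[which.max(sat_count)]]  # which.max: first (lexicographic) max
  terminal <- NA_character_
  if (satisfied[n]) {
    last_alts <- steps[[n]]$alternatives
    ok <- vapply(last_alts, function(req) all(req %in% gene_set), logical(1))
    ids <- sort(vapply(last_alts[ok], requirement_id, character(1)))
    terminal <- paste(ids, collapse = ",")
  }
  structure(list(pathway = definition$name, status = status,
                 missing_steps = missing_steps, satisfied = satisfied,
                 variant = variant, terminal = terminal),
            class = "pathway_call")
}

#' @export
print.pathway_call <- function(x, ...) {
  cat("<pathway_call> ", x$pathway, ": ", x$status, sep = "")
  if (length(x$missing_steps)) {
    cat(" (missing: ", paste(x$missing_steps, collapse = ", "), ")", sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Call pathways at MAG, genus or participant level
#'
#' Pools gene sets by the requested unit (a MAG's own genes; the union
#' over all MAGs sharing a genus label across the cohort; the union over
#' one participant's MAGs) and applies [call_pathway()] to each pooled
#' set. At participant level, a complete call with no single complete MAG
#' is flagged as a cooperation candidate: the pathway could only be run by
#' the community, not by any one genome.
#'
#' @param matrix A \code{presence_matrix}.
#' @param records MAG metadata (participant_id / genus_label per MAG).
#' @param definitions List of \code{pathway_definition}s.
#' @param level One of \code{"mag"}, \code{"genus"}, \code{"participant"}.
#' @return Data frame: unit_id, unit_level, pathway, status, variant
#'   (requirement ids joined by "|"), missing_steps (comma-joined),
#'   terminal, cooperation_candidate (logical; participant level only,
#'   otherwise NA).
#' @export
call_pathways_at_level <- function(matrix, records, definitions,
                                   level = c("mag", "genus", "participant")) {
  level <- match.arg(level)
  counts <- matrix$counts
  genes <- colnames(counts)
  mag_sets <- lapply(seq_len(nrow(counts)), function(i) genes[counts[i, ] >= 1L])
  names(mag_sets) <- rownames(counts)
  if (level == "mag") {
    units <- mag_sets
  } else {
    idx <- match(rownames(counts), records$mag_id)
    if (anyNA(idx)) {
      stop("MAG(s) without metadata: ",
           paste(rownames(counts)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    key <- if (level == "genus") {
      g <- if ("genus_label" %in% names(records)) records$genus_label[idx] else NA_character_
      g[is.na(g) | g == ""] <- "unclassified"
      g
    } else {
      records$participant_id[idx]
    }
    units <- lapply(split(mag_sets, key), function(sets) unique(unlist(sets)))
  }
  out <- list()
  for (d in definitions) {
    for (u in names(units)) {
      pc <- call_pathway(units[[u]], d)
      coop <- NA
      if (level == "participant" && pc$status == "complete") {
        member_sets <- split(mag_sets, records$participant_id[match(rownames(counts), records$mag_id)])[[u]]
        any_mag_complete <- any(vapply(member_sets, function(s) {
          call_pathway(s, d)$status == "complete"
        }, logical(1)))
        coop <- !any_mag_complete
      }
      out[[length(out) + 1]] <- data.frame(
        unit_id = u, unit_level = level, pathway = d$name, status = pc$status,
        variant = paste(vapply(pc$variant, requirement_id, character(1)),
                        collapse = "|"),
        missing_steps = paste(pc$missing_steps, collapse = ","),
        terminal = pc$terminal,
        cooperation_candidate = coop,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pairwise gene co-occurrence across MAGs
#'
#' @param matrix A \code{presence_matrix}.
#' @param symbol_a,symbol_b Gene symbols present in the matrix.
#' @return 2x2 integer matrix of MAG counts with rows (a present/absent)
#'   and columns (b present/absent); cells sum to the number of MAGs.
#' @export
cooccurrence_table <- function(matrix, symbol_a, symbol_b) {
  counts <- matrix$counts
  for (s in c(symbol_a, symbol_b)) {
    if (!s %in% colnames(counts)) {
      stop("unknown gene symbol: ", s, call. = FALSE)
    }
  }
  a <- counts[, symbol_a] >= 1L
  b <- counts[, symbol_b] >= 1L
  tab <- matrix(c(sum(a & b), sum(!a & b), sum(a & !b), sum(!a & !b)),
                nrow = 2,
                dimnames = list(paste0(symbol_a, c("+", "-")),
                                paste0(symbol_b, c("+", "-"))))
  storage.mode(tab) <- "integer"
  tab
}
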