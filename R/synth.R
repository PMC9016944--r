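#' Configure a synthetic MAG cohort
#'
#' Describes a cohort of participants across the three colorectal disease
#' states, each contributing a set of MAGs whose gene carriage is
#' genus-structured: every MAG draws a genus from a weighted pool and
#' inherits that genus's per-gene carriage probabilities. Disease-state
#' effects act multiplicatively on the carriage *odds* (so a logistic
#' alternative is literally realizable and planted odds ratios are
#' recoverable by the score test). Defaults mirror the published cohort
#' scale of roughly 25 MAGs per participant; calibration studies use
#' smaller cohorts.
#'
#' @param n_per_state Named integer vector: participants per state
#'   (names healthy, adenoma, carcinoma).
#' @param genus_pool List with \code{genus} (labels), \code{weight}
#'   (sampling weights, >= 0, not all zero) and \code{carriage} (matrix
#'   genera x genes of per-MAG carriage probabilities in [0,1], colnames =
#'   gene symbols). See [random_genus_pool()].
#' @param mags_per_participant Distribution spec: a list with
#'   \code{family} in \code{c("nbinom", "poisson", "fixed")} and its
#'   parameters (\code{mu}/\code{size}, \code{lambda}, or \code{k}).
#' @param effects Matrix genes x states of multiplicative odds effects on
#'   carriage (1 = null). Default all 1.
#' @param stage_distribution Probabilities over stages I-IV for carcinoma
#'   participants.
#' @param copy_lambda Poisson mean for extra gene copies within a carrying
#'   MAG (counts are 1 + Pois(copy_lambda); default 0, i.e. single copy).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return Validated list of class \code{cohort_config}.
#' @export
cohort_config <- function(n_per_state = c(healthy = 20, adenoma = 20, carcinoma = 20),
                          genus_pool,
                          mags_per_participant = list(family = "nbinom", mu = 25, size = 10),
                          effects = NULL,
                          stage_distribution = c(I = 0.2, II = 0.3, III = 0.3, IV = 0.2),
                          copy_lambda = 0,
                          seed = 1L) {
  if (!all(c("healthy", "adenoma", "carcinoma") %in% names(n_per_state))) {
    stop("config validation error: n_per_state needs healthy/adenoma/carcinoma",
         call. = FALSE)
  }
  genes <- colnames(genus_pool$carriage)
  if (is.null(genes)) {
    stop("config validation error: genus_pool$carriage needs gene colnames",
         call. = FALSE)
  }
  if (any(genus_pool$carriage < 0 | genus_pool$carriage > 1)) {
    stop("config validation error: carriage probabilities outside [0, 1]",
         call. = FALSE)
  }
  if (any(genus_pool$weight < 0) || sum(genus_pool$weight) <= 0) {
    stop("config validation error: genus weights must be >= 0, not all zero",
         call. = FALSE)
  }
  fam <- mags_per_participant$family
  if (!fam %in% c("nbinom", "poisson", "fixed")) {
    stop("config validation error: unknown distribution family '", fam, "'",
         call. = FALSE)
  }
  if (fam == "nbinom" &&
      (is.null(mags_per_participant$mu) || is.null(mags_per_participant$size) ||
       mags_per_participant$mu <= 0 || mags_per_participant$size <= 0)) {
    stop("config validation error: nbinom needs mu > 0 and size > 0",
         call. = FALSE)
  }
  if (fam == "poisson" && (is.null(mags_per_participant$lambda) ||
                           mags_per_participant$lambda <= 0)) {
    stop("config validation error: poisson needs lambda > 0", call. = FALSE)
  }
  if (fam == "fixed" && (is.null(mags_per_participant$k) ||
                         mags_per_participant$k < 0)) {
    stop("config validation error: fixed needs k >= 0", call. = FALSE)
  }
  if (is.null(effects)) {
    effects <- matrix(1, nrow = length(genes), ncol = 3,
                      dimnames = list(genes, DISEASE_STATES))
  }
  if (!identical(rownames(effects), genes) ||
      !identical(colnames(effects), DISEASE_STATES)) {
    stop("config validation error: effects must be genes x ",
         "(healthy, adenoma, carcinoma) with matching dimnames", call. = FALSE)
  }
  if (any(effects <= 0)) {
    stop("config validation error: effects must be > 0", call. = FALSE)
  }
  if (abs(sum(stage_distribution) - 1) > 1e-8 || any(stage_distribution < 0) ||
      !all(c("I", "II", "III", "IV") %in% names(stage_distribution))) {
    stop("config validation error: stage_distribution must be probabilities ",
         "over I-IV summing to 1", call. = FALSE)
  }
  structure(list(n_per_state = n_per_state, genus_pool = genus_pool,
                 mags_per_participant = mags_per_participant,
                 effects = effects, stage_distribution = stage_distribution,
                 copy_lambda = copy_lambda, seed = as.integer(seed),
                 genes = genes),
            class = "cohort_config")
}

#' Draw a random genus pool
#'
#' Builds a genus pool with log-uniform-ish sampling weights and per-gene
#' carriage probabilities drawn uniformly from \code{p_range}, so genes
#' "travel with genera" (carriage is correlated within a genus across
#' MAGs). Deterministic given the seed.
#'
#' @param genes Gene symbols (columns of the carriage matrix).
#' @param n_genera Number of genera.
#' @param seed Integer seed.
#' @param p_range Range of per-MAG carriage probabilities.
#' @param genus_labels Optional labels; default Genus01..GenusNN.
#' @return Genus-pool list for [cohort_config()].
#' @export
random_genus_pool <- function(genes, n_genera = 12, seed = 1L,
                              p_range = c(0, 0.2), genus_labels = NULL) {
  if (is.null(genus_labels)) {
    genus_labels <- sprintf("Genus%02d", seq_len(n_genera))
  }
  withr::with_seed(as.integer(seed), {
    weight <- exp(stats::runif(n_genera, 0, 2))
    carriage <- matrix(stats::runif(n_genera * length(genes),
                                    p_range[1], p_range[2]),
                       nrow = n_genera,
                       dimnames = list(genus_labels, genes))
    list(genus = genus_labels, weight = weight, carriage = carriage)
  })
}

odds_adjust <- function(p, effect) {
  # multiply carriage odds by `effect`, return as probability
  p * effect / (1 - p + p * effect)
}

#' True per-gene, per-state carriage probabilities of a config
#'
#' Closed-form marginal per-MAG carriage probability for each gene and
#' disease state: the genus-weight mixture of the genus carriage
#' probabilities after applying the state's odds effect. These are the
#' recovery targets for calibration and power studies.
#'
#' @param config A \code{cohort_config}.
#' @return Data frame: gene, disease_state, prob.
#' @export
planted_effect_truth <- function(config) {
  pool <- config$genus_pool
  w <- pool$weight / sum(pool$weight)
  out <- list()
  for (s in DISEASE_STATES) {
    adj <- odds_adjust(pool$carriage,
                       rep(config$effects[, s], each = nrow(pool$carriage)))
    marg <- colSums(adj * w)
    out[[length(out) + 1]] <- data.frame(
      gene = config$genes, disease_state = s, prob = unname(marg),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Generate a synthetic cohort
#'
#' Samples participants, their disease states and stages, per-participant
#' MAG counts, per-MAG genus labels and genus-structured gene carriage
#' with state effects applied on the odds scale. Byte-identical across
#' runs for a fixed config (including seed).
#'
#' @param config A \code{cohort_config}.
#' @return List of class \code{synthetic_cohort}: \code{records} (MAG
#'   metadata data frame), \code{matrix} (a \code{presence_matrix} over
#'   all MAGs, including any participant's empty set), \code{config}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  genes <- config$genes
  pool <- config$genus_pool
  withr::with_seed(config$seed, {
    n_state <- config$n_per_state[DISEASE_STATES]
    n_p <- sum(n_state)
    state <- rep(DISEASE_STATES, times = n_state)
    pid <- sprintf("P%04d", seq_len(n_p))
    stage <- rep(NA_character_, n_p)
    is_ca <- state == "carcinoma"
    if (any(is_ca)) {
      stage[is_ca] <- sample(c("I", "II", "III", "IV"), sum(is_ca),
                             replace = TRUE,
                             prob = config$stage_distribution[c("I", "II", "III", "IV")])
    }
    mp <- config$mags_per_participant
    n_mags <- switch(mp$family,
      nbinom = stats::rnbinom(n_p, mu = mp$mu, size = mp$size),
      poisson = stats::rpois(n_p, lambda = mp$lambda),
      fixed = rep(as.integer(mp$k), n_p))
    total <- sum(n_mags)
    owner <- rep(seq_len(n_p), times = n_mags)
    mag_id <- if (total > 0) {
      paste0(pid[owner], "-MAG",
             unlist(lapply(n_mags, seq_len), use.names = FALSE))
    } else character(0)
    genus_idx <- sample(seq_along(pool$genus), total, replace = TRUE,
                        prob = pool$weight)
    state_idx <- match(state[owner], DISEASE_STATES)
    # per-MAG carriage probability with state effect on the odds scale
    base_p <- pool$carriage[genus_idx, , drop = FALSE]
    eff <- t(config$effects)[state_idx, , drop = FALSE]
    padj <- odds_adjust(base_p, eff)
    present <- matrix(stats::rbinom(length(padj), 1L, padj),
                      nrow = total, ncol = length(genes),
                      dimnames = list(mag_id, genes))
    counts <- present
    if (config$copy_lambda > 0) {
      extra <- matrix(stats::rpois(length(padj), config$copy_lambda),
                      nrow = total, ncol = length(genes))
      counts <- present * (1L + extra)
    }
    records <- data.frame(
      mag_id = mag_id,
      participant_id = pid[owner],
      study = rep("synthetic", total),
      disease_state = state[owner],
      stage = stage[owner],
      genus_label = pool$genus[genus_idx],
      completeness = round(stats::runif(total, 55, 100), 2),
      contamination = round(stats::runif(total, 0, 4.5), 2),
      strain_heterogeneity = round(stats::runif(total, 0, 3), 2),
      stringsAsFactors = FALSE)
    participants <- data.frame(participant_id = pid, disease_state = state,
                               stage = stage, n_mags = n_mags,
                               stringsAsFactors = FALSE)
    structure(list(records = records,
                   matrix = new_presence_matrix(counts),
                   participants = participants,
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$participants), " participants, ",
      nrow(x$records), " MAGs, ", length(x$config$genes), " genes (seed ",
      x$config$seed, ")\n", sep = "")
  invisible(x)
}

#' Binarize a synthetic cohort to participant profiles
#'
#' Convenience wrapper: every participant appears, including those whose
#' MAG count is zero.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @return A \code{participant_profiles} object.
#' @export
cohort_profiles <- function(cohort) {
  recs <- cohort$records
  # append zero-MAG participants so denominators stay complete
  missing <- setdiff(cohort$participants$participant_id, recs$participant_id)
  profiles <- binarize_by_participant(cohort$matrix, recs)
  if (length(missing) > 0) {
    pinfo <- cohort$participants
    add <- pinfo[match(missing, pinfo$participant_id), ]
    info <- rbind(profiles$info,
                  data.frame(participant_id = add$participant_id,
                             disease_state = add$disease_state,
                             stage = add$stage, n_mags = 0L,
                             stringsAsFactors = FALSE))
    zero <- matrix(0L, nrow = length(missing), ncol = ncol(profiles$presence),
                   dimnames = list(missing, colnames(profiles$presence)))
    profiles$presence <- rbind(profiles$presence, zero >= 1L)
    profiles$mags_with_gene <- rbind(profiles$mags_with_gene, zero)
    ord <- match(cohort$participants$participant_id, info$participant_id)
    profiles$info <- info[ord, ]
    rownames(profiles$info) <- NULL
    profiles$presence <- profiles$presence[info$participant_id[ord], , drop = FALSE]
    profiles$mags_with_gene <- profiles$mags_with_gene[info$participant_id[ord], , drop = FALSE]
  }
  profiles
}

#' Write a synthetic cohort as an hmmsearch tblout fixture
#'
#' Emits a valid tblout file: one row per gene copy per carrying MAG, with
#' full-sequence bit score set above the gene's trusted cutoff (cutoff +
#' 25; 100 for genes without a cutoff). With \code{decoy_margin} set, one
#' decoy row is added for every absent (MAG, gene) cell whose gene has a
#' trusted cutoff, scored exactly \code{cutoff - decoy_margin}, so
#' trusted-cutoff filtering must remove every decoy and the parsed,
#' filtered file reproduces the generating presence matrix exactly.
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param catalog A \code{gene_catalog} supplying hmm ids and cutoffs.
#' @param path Output file path.
#' @param decoy_margin Positive bit-score margin below the cutoff for
#'   decoy rows, or NULL (default) for no decoys.
#' @return \code{path}, invisibly.
#' @export
write_tblout_fixture <- function(cohort, catalog, path, decoy_margin = NULL) {
  counts <- cohort$matrix$counts
  genes <- colnames(counts)
  rows <- catalog_lookup(catalog, genes)
  cutoff <- rows$trusted_cutoff
  hmm_id <- rows$hmm_id
  score_present <- ifelse(is.na(cutoff), 100, cutoff + 25)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "#                                                               --- full sequence ---- --- best 1 domain ---- --- domain number estimation ----",
    "# target name        accession  query name           accession    E-value  score  bias   E-value  score  bias   exp reg clu  ov env dom rep inc description of target",
    "#------------------- ---------- -------------------- ---------- --------- ------ ----- --------- ------ ----- ---- --- --- --- --- --- --- --- ---------------------"),
    con)
  fmt <- "%s - %s - %.1e %.1f 0.0 %.1e %.1f 0.0 1.0 1 0 0 1 1 1 1 -"
  for (i in seq_len(nrow(counts))) {
    mag <- rownames(counts)[i]
    orf <- 0L
    for (j in seq_along(genes)) {
      k <- counts[i, j]
      if (k >= 1L) {
        for (copy in seq_len(k)) {
          orf <- orf + 1L
          writeLines(sprintf(fmt, paste0(mag, "_", orf), hmm_id[j],
                             1e-30, score_present[j], 1e-30,
                             score_present[j]), con)
        }
      } else if (!is.null(decoy_margin) && !is.na(cutoff[j])) {
        orf <- orf + 1L
        writeLines(sprintf(fmt, paste0(mag, "_", orf), hmm_id[j],
                           1e-3, cutoff[j] - decoy_margin, 1e-3,
                           cutoff[j] - decoy_margin), con)
      }
    }
  }
  invisible(path)
}

#' Write all cohort input files
#'
#' Emits the full pipeline input set for a synthetic cohort: MAG metadata
#' TSV, wide presence table, tblout fixture and a YAML manifest recording
#' the seed and sizes (no timestamps, so identical configs give
#' byte-identical output trees).
#'
#' @param cohort A \code{synthetic_cohort}.
#' @param dir Output directory (created if needed).
#' @param catalog A \code{gene_catalog} for the tblout writer.
#' @param decoy_margin Passed to [write_tblout_fixture()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir, catalog, decoy_margin = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(metadata = file.path(dir, "mag_metadata.tsv"),
             presence = file.path(dir, "presence_table.tsv"),
             tblout = file.path(dir, "hits.tblout"),
             manifest = file.path(dir, "manifest.yaml"))
  write_mag_metadata(cohort$records, paths[["metadata"]])
  write_presence_table(cohort$matrix, paths[["presence"]])
  write_tblout_fixture(cohort, catalog, paths[["tblout"]],
                       decoy_margin = decoy_margin)
  yaml::write_yaml(list(
    seed = cohort$config$seed,
    n_participants = nrow(cohort$participants),
    n_mags = nrow(cohort$records),
    n_genes = length(cohort$config$genes),
    decoy_margin = if (is.null(decoy_margin)) "none" else decoy_margin,
    package_version = as.character(utils::packageVersion("gutsulfur"))),
    paths[["manifest"]])
  invisible(paths)
}

#' Type-I error of the state association test on null cohorts
#'
#' Generates \code{n_runs} cohorts from a null config (all effects 1),
#' binarizes to participants and runs the 2x3 chi-squared test per gene;
#' returns the raw rejection rate at \code{alpha} over all non-degenerate
#' tests plus the pooled p-values (for uniformity checks). Run seeds are
#' \code{seed + 1 .. seed + n_runs}.
#'
#' @param config A null \code{cohort_config}.
#' @param n_runs Number of cohorts.
#' @param alpha Nominal level (default 0.05).
#' @param seed Base seed.
#' @return List: rejection_rate, n_tests, p_values.
#' @export
null_calibration <- function(config, n_runs, alpha = 0.05, seed = 1L) {
  if (any(config$effects != 1)) {
    stop("null_calibration needs a null config (all effects 1)", call. = FALSE)
  }
  pvals <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    cohort <- generate_cohort(cfg)
    profiles <- cohort_profiles(cohort)
    p <- vapply(config$genes, function(g) {
      res <- chi_squared_test(build_contingency(profiles, g))
      if (res$degenerate) NA_real_ else res$p_raw
    }, numeric(1))
    pvals[[r]] <- p
  }
  p_all <- unlist(pvals)
  p_all <- p_all[!is.na(p_all)]
  list(rejection_rate = mean(p_all < alpha), n_tests = length(p_all),
       p_values = p_all)
}

#' Recovery rate of a planted state effect
#'
#' Generates \code{n_runs} cohorts from a config with one planted gene
#' effect and counts the runs in which that gene attains the minimum
#' BH-adjusted p-value across the family *and* its direction (state of
#' maximal carrier proportion) equals the planted state.
#'
#' @param config A \code{cohort_config} with the planted effect.
#' @param gene The planted gene symbol.
#' @param state The planted disease state.
#' @param n_runs Number of cohorts.
#' @param seed Base seed.
#' @return List: recovery_rate, direction_rate (direction correct
#'   regardless of rank), hits (logical per run).
#' @export
planted_recovery <- function(config, gene, state, n_runs, seed = 1L) {
  hits <- logical(n_runs)
  dir_ok <- logical(n_runs)
  for (r in seq_len(n_runs)) {
    cfg <- config
    cfg$seed <- as.integer(seed + r)
    cohort <- generate_cohort(cfg)
    profiles <- cohort_profiles(cohort)
    res <- associate_all(profiles)
    row <- res[res$feature == gene, ]
    dir_ok[r] <- row$direction == state
    hits[r] <- dir_ok[r] && row$p_adj <= min(res$p_adj)
  }
  list(recovery_rate = mean(hits), direction_rate = mean(dir_ok), hits = hits)
}
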