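#' Build a 2x3 presence/absence-by-state contingency table for one gene
#'
#' @param profiles A \code{participant_profiles} object.
#' @param gene Gene symbol (a column of the presence matrix).
#' @return 2x3 integer matrix, rows \code{presence}/\code{absence},
#'   columns the disease states present in the cohort (in the order
#'   healthy, adenoma, carcinoma). Column sums equal state sizes.
#' @export
build_contingency <- function(profiles, gene) {
  if (!gene %in% colnames(profiles$presence)) {
    stop("unknown gene symbol: ", gene, call. = FALSE)
  }
  states <- DISEASE_STATES[DISEASE_STATES %in% profiles$info$disease_state]
  if (length(states) < 2) {
    stop("contingency error: need >= 2 disease states with participants",
         call. = FALSE)
  }
  pres <- profiles$presence[, gene]
  state <- factor(profiles$info$disease_state, levels = states)
  tab <- rbind(presence = tapply(pres, state, sum),
               absence = tapply(!pres, state, sum))
  storage.mode(tab) <- "integer"
  tab
}

#' Pearson chi-squared test of independence on a contingency table
#'
#' Plain Pearson statistic \eqn{\sum (O-E)^2/E} with expected counts from
#' the row/column margins; no continuity correction and no
#' small-expected-count exclusion (the smallest expected count is
#' surfaced as \code{expected_min} so users can judge the approximation).
#' For a 2x3 table df = 2 and the upper-tail p-value equals
#' \eqn{\exp(-\chi^2/2)}. A zero row margin (gene absent everywhere, or
#' present everywhere) yields a degenerate result: statistic 0, p 1,
#' \code{degenerate = TRUE}.
#'
#' @param table Non-negative count matrix (rows x columns).
#' @return List: statistic, df, p_raw, expected_min, degenerate.
#' @export
chi_squared_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("negative counts", call. = FALSE)
  rs <- rowSums(table); cs <- colSums(table); n <- sum(table)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  if (n == 0 || any(cs == 0)) {
    stop("chi-squared error: zero column margin or empty table", call. = FALSE)
  }
  if (any(rs == 0)) {
    return(list(statistic = 0, df = df, p_raw = 1,
                expected_min = min(outer(rs, cs) / n), degenerate = TRUE))
  }
  expected <- outer(rs, cs) / n
  statistic <- sum((table - expected)^2 / expected)
  list(statistic = statistic, df = df,
       p_raw = stats::pchisq(statistic, df = df, lower.tail = FALSE),
       expected_min = min(expected), degenerate = FALSE)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment \eqn{q_{(i)} = \min_{j \ge i} (m p_{(j)} / j)}
#' clipped to 1, returned in input order (delegates to
#' \code{stats::p.adjust(method = "BH")} after validating the inputs).
#'
#' @param p_raw Numeric vector of raw p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
benjamini_hochberg <- function(p_raw) {
  if (length(p_raw) == 0) return(numeric(0))
  if (any(is.na(p_raw)) || any(p_raw < 0 | p_raw > 1)) {
    stop("p-value validation error: values must be in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_raw, method = "BH")
}

#' Rao score test for a stage trend in gene carriage
#'
#' Tests slope = 0 in the binomial logistic model
#' \eqn{\mathrm{logit} P(\mathrm{presence}) = \beta_0 + \beta_1 x}
#' where \eqn{x} is the (numeric) stage coding. The score statistic is
#' evaluated at the intercept-only fit in closed form:
#' \eqn{U = \sum x_i (y_i - \bar y)},
#' \eqn{V = \bar y (1 - \bar y) \sum (x_i - \bar x)^2},
#' statistic \eqn{U^2 / V}, compared to chi-squared with 1 df. When every
#' participant has the same presence value (or the stages are constant)
#' the test is degenerate: statistic 0, p 1, \code{degenerate = TRUE}.
#'
#' @param presence Logical (or 0/1) vector, one entry per participant.
#' @param stage Stage per participant: Roman numerals \code{I..IV}, or a
#'   numeric coding.
#' @param coding Numeric scores for stages I-IV; the default is the
#'   equally-spaced coding 1:4.
#' @return List: statistic, df (1), p_raw, degenerate.
#' @export
stage_score_test <- function(presence, stage,
                             coding = c(I = 1, II = 2, III = 3, IV = 4)) {
  y <- as.numeric(presence)
  x <- if (is.numeric(stage)) as.numeric(stage) else {
    v <- unname(coding[as.character(stage)])
    if (anyNA(v)) {
      stop("stage validation error: unknown stage token(s): ",
           paste(unique(stage[is.na(v)]), collapse = ", "), call. = FALSE)
    }
    v
  }
  if (length(y) != length(x)) stop("length mismatch", call. = FALSE)
  if (length(unique(x)) < 2) {
    stop("stage score test error: need >= 2 distinct stages", call. = FALSE)
  }
  ybar <- mean(y)
  if (ybar == 0 || ybar == 1) {
    return(list(statistic = 0, df = 1L, p_raw = 1, degenerate = TRUE))
  }
  U <- sum(x * (y - ybar))
  V <- ybar * (1 - ybar) * sum((x - mean(x))^2)
  statistic <- U^2 / V
  list(statistic = statistic, df = 1L,
       p_raw = stats::pchisq(statistic, df = 1, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Per-stage carrier proportions for one gene
#'
#' Carrier proportion per cancer stage, normalized to the number of
#' participants in that stage. Unstaged participants are excluded from
#' denominators; stages with zero participants are omitted (not reported
#' as zero).
#'
#' @param profiles A \code{participant_profiles} object.
#' @param gene Gene symbol.
#' @param states Disease states whose participants enter the profile
#'   (default carcinoma only, where staging applies).
#' @return Data frame: gene, stage, n_stage, n_carriers, prop_carriers.
#' @export
stage_profile <- function(profiles, gene, states = "carcinoma") {
  info <- profiles$info
  pres <- profiles$presence[, gene]
  in_scope <- info$disease_state %in% states &
    !is.na(info$stage) & info$stage %in% c("I", "II", "III", "IV")
  out <- list()
  for (s in c("I", "II", "III", "IV")) {
    sel <- in_scope & info$stage == s
    if (!any(sel)) next
    out[[length(out) + 1]] <- data.frame(
      gene = gene, stage = s, n_stage = sum(sel),
      n_carriers = sum(pres[sel]),
      prop_carriers = sum(pres[sel]) / sum(sel),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0) {
    return(data.frame(gene = character(0), stage = character(0),
                      n_stage = integer(0), n_carriers = integer(0),
                      prop_carriers = numeric(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

significance_marker <- function(p_adj) {
  ifelse(p_adj < 0.001, "***",
         ifelse(p_adj < 0.01, "**", ifelse(p_adj < 0.05, "*", "")))
}

#' Test every gene's presence against disease state
#'
#' Runs the 2x3 Pearson chi-squared test for each feature and applies a
#' single Benjamini-Hochberg pass across the whole feature family.
#' \code{direction} is the disease state with the maximal carrier
#' proportion (ties broken toward the more advanced state). Significance
#' markers (*, **, ***) annotate adjusted p below 0.05 / 0.01 / 0.001.
#'
#' @param profiles A \code{participant_profiles} object.
#' @param genes Features to test (default: all genes in the profiles).
#' @return Data frame: feature, statistic, df, p_raw, p_adj, direction,
#'   expected_min, degenerate, signif.
#' @export
associate_all <- function(profiles, genes = colnames(profiles$presence)) {
  genes <- as.character(genes)
  if (length(genes) == 0) {
    return(data.frame(feature = character(0), statistic = numeric(0),
                      df = integer(0), p_raw = numeric(0), p_adj = numeric(0),
                      direction = character(0), expected_min = numeric(0),
                      degenerate = logical(0), signif = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(genes, function(g) {
    tab <- build_contingency(profiles, g)
    res <- chi_squared_test(tab)
    prop <- tab["presence", ] / colSums(tab)
    # ties toward the more advanced state: scan from carcinoma backwards
    ord <- rev(seq_along(prop))
    direction <- colnames(tab)[ord[which.max(prop[ord])]]
    data.frame(feature = g, statistic = res$statistic, df = res$df,
               p_raw = res$p_raw, direction = direction,
               expected_min = res$expected_min, degenerate = res$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_hochberg(out$p_raw)
  out$signif <- significance_marker(out$p_adj)
  out[, c("feature", "statistic", "df", "p_raw", "p_adj", "direction",
          "expected_min", "degenerate", "signif")]
}

#' Test every gene's presence against cancer stage
#'
#' Runs [stage_score_test()] per gene over the staged participants of the
#' selected disease states and applies one Benjamini-Hochberg pass.
#'
#' @param profiles A \code{participant_profiles} object.
#' @param genes Features to test (default: all).
#' @param states Disease states included (default carcinoma only; pass
#'   \code{c("healthy","adenoma","carcinoma")} to pool, with unstaged
#'   participants still excluded).
#' @param coding Stage scores passed to [stage_score_test()].
#' @return Data frame: feature, statistic, df, p_raw, p_adj, degenerate,
#'   signif.
#' @export
associate_stage <- function(profiles, genes = colnames(profiles$presence),
                            states = "carcinoma",
                            coding = c(I = 1, II = 2, III = 3, IV = 4)) {
  info <- profiles$info
  sel <- info$disease_state %in% states &
    !is.na(info$stage) & info$stage %in% names(coding)
  if (sum(sel) == 0) stop("no staged participants in scope", call. = FALSE)
  rows <- lapply(as.character(genes), function(g) {
    res <- stage_score_test(profiles$presence[sel, g], info$stage[sel],
                            coding = coding)
    data.frame(feature = g, statistic = res$statistic, df = res$df,
               p_raw = res$p_raw, degenerate = res$degenerate,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- benjamini_hochberg(out$p_raw)
  out$signif <- significance_marker(out$p_adj)
  out[, c("feature", "statistic", "df", "p_raw", "p_adj", "degenerate",
          "signif")]
}
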